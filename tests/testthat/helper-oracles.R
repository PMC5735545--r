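# Independent oracles used to pin implementation behavior. Each is written
# against first principles (enumeration, quadrature, direct linear algebra),
# deliberately sharing no code path with the implementation it checks.

# Mk likelihood by explicit enumeration over all internal-node state
# assignments; transition matrices via Matrix::expm (scaling-and-squaring),
# not the package's eigendecomposition route.
oracle_mk_loglik <- function(tree, tip_priors, Q, root_prior = NULL) {
  k <- nrow(Q)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  tp <- tip_priors[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_state <- function(nd) {
      if (nd <= n) NA_integer_ else grid[g, nd - n]
    }
    pr <- root_prior[grid[g, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- assign_state(par)
      if (ch <= n) {
        pr <- pr * sum(P[[e]][sp, ] * tp[ch, ])
      } else {
        pr <- pr * P[[e]][sp, assign_state(ch)]
      }
    }
    total <- total + pr
  }
  log(total)
}

# Marginal node posteriors by Bayes rule over the same enumeration.
oracle_marginal <- function(tree, tip_priors, Q, root_prior = NULL) {
  k <- nrow(Q)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  tp <- tip_priors[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  post <- matrix(0, m, k)
  for (g in seq_len(nrow(grid))) {
    pr <- root_prior[grid[g, 1]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sp <- grid[g, par - n]
      if (ch <= n) pr <- pr * sum(P[[e]][sp, ] * tp[ch, ])
      else pr <- pr * P[[e]][sp, grid[g, ch - n]]
    }
    for (nd in seq_len(m)) post[nd, grid[g, nd]] <- post[nd, grid[g, nd]] + pr
  }
  post / rowSums(post)
}

# Expected number of (true) transitions on a single branch conditional on its
# endpoint states: E[N | a, b, t] = sum_{i != j} q_ij
#   int_0^t P_ai(u) P_jb(t - u) du / P_ab(t), by numerical quadrature with
# Matrix::expm transition probabilities.
oracle_branch_expected_transitions <- function(Q, a, b, t) {
  k <- nrow(Q)
  Pt <- function(u) as.matrix(Matrix::expm(Q * u))
  pab <- Pt(t)[a, b]
  total <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || Q[i, j] <= 0) next
    f <- Vectorize(function(u) Pt(u)[a, i] * Pt(t - u)[j, b])
    total <- total + Q[i, j] * stats::integrate(f, 0, t, rel.tol = 1e-9)$value
  }
  total / pab
}

# Multivariate-normal log density via solve()/determinant(), sharing nothing
# with the Cholesky path in the package.
oracle_mvn_loglik <- function(y, mean, Sigma) {
  d <- y - mean
  q <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (q * log(2 * pi) + ld + drop(d %*% solve(Sigma, d)))
}

# Brute-force OU/BM/EB covariance and mean by quadrature along branches,
# using full matrix exponentials (no eigendecomposition shortcut).
oracle_model_loglik <- function(tree, X, params, painting = NULL, n_quad = 801) {
  kind <- params$kind
  n <- length(tree$tip.label); p <- ncol(X)
  X <- X[tree$tip.label, , drop = FALSE]
  if (kind %in% c("BM", "EB")) {
    r <- if (kind == "EB") params$r else 0
    C <- ape::vcv(tree)
    if (r != 0) C <- (exp(r * C) - 1) / r
    Sigma <- kronecker(C, params$R)
    mvec <- rep(params$mu0, n)
    return(oracle_mvn_loglik(as.vector(t(X)), mvec, Sigma))
  }
  A <- params$A; R <- params$R
  expmA <- function(t) as.matrix(Matrix::expm(-A * t))
  simpson <- function(f, lo, hi, m = n_quad) {
    if (hi <= lo) return(matrix(0, p, p))
    if (m %% 2 == 0) m <- m + 1
    us <- seq(lo, hi, length.out = m); h <- us[2] - us[1]
    wts <- c(1, rep(c(4, 2), (m - 3) / 2), 4, 1)
    out <- matrix(0, p, p)
    for (i in seq_along(us)) out <- out + wts[i] * f(us[i])
    out * h / 3
  }
  dep <- tree_depths_oracle(tree)
  Tht <- max(dep[seq_len(n)])
  M <- ape::mrca(tree)
  Sigma <- matrix(0, n * p, n * p)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- if (i == j) Tht else dep[M[i, j]]
    V <- simpson(function(u) expmA(u) %*% R %*% t(expmA(u)), 0, s)
    blk <- expmA(Tht - s) %*% V %*% t(expmA(Tht - s))
    Sigma[(i - 1) * p + seq_len(p), (j - 1) * p + seq_len(p)] <- blk
  }
  # means
  if (kind == "OU1") {
    mvec <- rep(as.numeric(params$theta), n)
  } else {
    theta <- params$theta
    parent <- integer(n + tree$Nnode); parent[tree$edge[, 2]] <- tree$edge[, 1]
    eoc <- match(seq_len(n + tree$Nnode), tree$edge[, 2])
    rootreg <- painting$states[painting$node_states[n + 1]]
    mvec <- numeric(n * p)
    for (tip in seq_len(n)) {
      path <- integer(0); nd <- tip
      while (nd != n + 1) { path <- c(nd, path); nd <- parent[nd] }
      mval <- expmA(Tht) %*% theta[rootreg, ]
      t0 <- 0
      for (ch in path) {
        em <- painting$edge_maps[[eoc[ch]]]
        for (si in seq_along(em)) {
          t1 <- t0 + em[si]
          acc <- simpson(function(u) expmA(Tht - u) %*% A, t0, t1, 401)
          mval <- mval + acc %*% theta[names(em)[si], ]
          t0 <- t1
        }
      }
      mvec[(tip - 1) * p + seq_len(p)] <- mval
    }
  }
  oracle_mvn_loglik(as.vector(t(X)), mvec, Sigma)
}

# Node depths without using the package internals.
tree_depths_oracle <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      val <- depth[par] + tree$edge.length[e]
      if (abs(depth[ch] - val) > 0) { depth[ch] <- val; done <- FALSE }
    }
    if (done) break
  }
  depth
}

# Kendall tau-b by direct concordant/discordant pair enumeration.
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1
    if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# Indicator-matrix MCA by an eigendecomposition route (no svd()).
oracle_mca <- function(m) {
  m <- as.data.frame(m, stringsAsFactors = FALSE)
  Z <- do.call(cbind, lapply(m, function(col) {
    f <- factor(col)
    stats::model.matrix(~ f - 1)
  }))
  P <- Z / sum(Z)
  r <- rowSums(P); cmass <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cmass) %*% diag(1 / sqrt(cmass))
  ev <- eigen(S %*% t(S), symmetric = TRUE)
  keep <- ev$values > 1e-10
  lambda <- ev$values[keep]
  Fc <- diag(1 / sqrt(r)) %*% ev$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(lambda), sum(keep))
  list(eigenvalues = lambda, row_coords = Fc)
}

# Wilks' Lambda by direct eigendecomposition of W^{-1} B.
oracle_wilks <- function(X, groups) {
  X <- as.matrix(X); groups <- droplevels(factor(groups))
  gm <- colMeans(X)
  W <- matrix(0, ncol(X), ncol(X)); B <- W
  for (lv in levels(groups)) {
    Xi <- X[groups == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - gm)
  }
  ev <- eigen(solve(W) %*% B, only.values = TRUE)$values
  prod(1 / (1 + Re(ev)))
}

# Random small fixtures
random_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

random_Q <- function(k, rate = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- matrix(stats::runif(k * k, 0.2, 1.5) * rate, k, k)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

unit_tip_priors <- function(states_vec, k, taxa) {
  tp <- matrix(0, length(states_vec), k, dimnames = list(taxa, NULL))
  tp[cbind(seq_along(states_vec), states_vec)] <- 1
  tp
}
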