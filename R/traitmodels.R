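#' Multivariate trait-evolution models: BM, EB, OU1, OUM
#'
#' Likelihood engine for multivariate Gaussian models of continuous trait
#' evolution on a phylogeny:
#'
#' * BM: Brownian motion with diffusion matrix R; tip covariance is the
#'   Kronecker product of the shared root-to-MRCA path-length matrix with R.
#' * EB: early burst; the BM rate decays as exp(r t) (r <= 0), so shared path
#'   lengths s are replaced by (exp(r s) - 1)/r.
#' * OU1 / OUM: Ornstein-Uhlenbeck with symmetric positive-definite selection
#'   matrix A and one optimum (OU1) or one optimum per habitat regime painted
#'   on the tree (OUM). The root state is fixed at the root-regime optimum
#'   (no root variance, not a free parameter), the convention recommended for
#'   trees of extant taxa only. On an ultrametric tree with A = U D U', tip
#'   covariance blocks in the eigenbasis are
#'   `R~_kl exp(-(d_k+d_l)(T-s)) (1-exp(-(d_k+d_l)s))/(d_k+d_l)`.
#'
#' `params` is a list with elements `kind` ("BM","EB","OU1","OUM"), `R` (p x p
#' SPD), and per kind: `mu0` (BM/EB root mean), `r` (EB), `A` (OU), `theta`
#' (OU1: p-vector; OUM: regimes x p matrix with regime rownames).
#'
#' @param tree Ultrametric `phylo` (BM/EB tolerate non-ultrametric trees).
#' @param traits Numeric matrix taxa x dimensions, rownames matching tips.
#' @param params Model parameter list (see Details).
#' @param painting `regime_painting` (required iff kind = "OUM").
#' @return Log-likelihood of the stacked trait vector.
#' @export
model_loglik <- function(tree, traits, params, painting = NULL) {
  X <- .align_traits(tree, traits)
  kind <- match.arg(params$kind, c("BM", "EB", "OU1", "OUM"))
  p <- ncol(X); n <- nrow(X)
  .check_spd(params$R, "R")
  if (kind %in% c("BM", "EB")) {
    r <- if (kind == "EB") params$r else 0
    if (kind == "EB" && r > 0) stop("EB requires r <= 0")
    C <- .eb_C(tree, r)
    mu0 <- params$mu0
    Sigma <- kronecker(C, params$R)
    y <- as.vector(t(X)) - rep(mu0, n)
    return(.chol_loglik(y, Sigma))
  }
  .check_spd(params$A, "A")
  if (kind == "OUM" && is.null(painting)) stop("OUM requires a regime painting")
  if (kind == "OU1") painting <- NULL  # single optimum: painting irrelevant
  mod <- .ou_rotated(tree, params$A, params$R, painting)
  theta_t <- if (kind == "OU1") {
    matrix(drop(crossprod(mod$U, as.numeric(params$theta))), 1, p)
  } else {
    th <- params$theta
    miss <- setdiff(mod$regimes, rownames(th))
    if (length(miss)) stop("painting regime(s) missing an optimum: ",
                           paste(miss, collapse = ", "))
    th[mod$regimes, , drop = FALSE] %*% mod$U
  }
  mvec <- as.vector(t(.ou_mean_rot(mod, theta_t)))
  yrot <- as.vector(t(X %*% mod$U)) - mvec
  .chol_loglik(yrot, mod$Sigma)
}

.align_traits <- function(tree, traits) {
  traits <- as.matrix(traits)
  rn <- normalize_labels(rownames(traits) %||% stop("traits need taxon rownames"))
  rownames(traits) <- rn
  missing <- setdiff(tree$tip.label, rn)
  if (length(missing)) stop("taxa missing traits: ", paste(missing, collapse = ", "))
  X <- traits[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop("traits must be complete (no NA)")
  if (any(apply(X, 2, stats::sd) == 0))
    stop("degenerate traits: zero variance in dimension(s) ",
         paste(which(apply(X, 2, stats::sd) == 0), collapse = ", "))
  X
}

.check_spd <- function(M, name) {
  if (is.null(M)) stop("missing ", name)
  if (!isSymmetric(unname(M), tol = 1e-8)) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("validation error: ", name, " not positive-definite")
  invisible(M)
}

# EB-transformed shared-path matrix; r = 0 gives plain BM paths.
.eb_C <- function(tree, r) {
  C <- ape::vcv(tree)
  if (r != 0) C <- (exp(r * C) - 1) / r
  C
}

# Gaussian log-density with zero mean and covariance Sigma (dense Cholesky).
.chol_loglik <- function(y, Sigma) {
  L <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  z <- backsolve(L, y, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# Tree/painting geometry reused across likelihood evaluations of one fit:
# MRCA depth matrix, height, and (for OUM) the root-to-tip segment table.
.ou_cache <- function(tree, painting = NULL) {
  if (!is_ultrametric(tree, rel_tol = 1e-3))
    stop("OU models require an ultrametric tree")
  n <- length(tree$tip.label)
  depth <- node_depths(tree)
  Tht <- max(depth[seq_len(n)])
  M <- ape::mrca(tree)
  sdep <- matrix(depth[M], n, n)
  diag(sdep) <- Tht
  out <- list(n = n, T = Tht, sdep = sdep)
  if (is.null(painting)) {
    out$regimes <- "theta"
    out$segtab <- NULL
  } else {
    regimes <- painting$regimes
    parent <- integer(n + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    edge_of_child <- match(seq_len(n + tree$Nnode), tree$edge[, 2])
    root <- n + 1L
    tip_v <- integer(0); reg_v <- integer(0); t0_v <- numeric(0); t1_v <- numeric(0)
    for (tip in seq_len(n)) {
      path <- integer(0); nd <- tip
      while (nd != root) { path <- c(nd, path); nd <- parent[nd] }
      t0 <- 0
      for (ch in path) {
        em <- painting$edge_maps[[edge_of_child[ch]]]
        for (si in seq_along(em)) {
          t1 <- t0 + em[si]
          tip_v <- c(tip_v, tip)
          reg_v <- c(reg_v, match(names(em)[si], regimes))
          t0_v <- c(t0_v, t0); t1_v <- c(t1_v, t1)
          t0 <- t1
        }
      }
    }
    out$regimes <- regimes
    out$segtab <- list(tip = tip_v, regime = reg_v, t0 = t0_v, t1 = t1_v)
    out$root_regime <- match(painting$states[painting$node_states[root]], regimes)
  }
  out
}

# Rotated-basis OU machinery. Works in the eigenbasis of A so the np x np
# covariance factorizes into p^2 scalar kernels of the MRCA depth matrix.
# Returns Sigma (rotated), U, d, regimes, W (tip x regime x eigendim mean
# weights; includes the root term), T (height).
.ou_rotated <- function(tree, A, R, painting = NULL, cache = NULL) {
  cache <- cache %||% .ou_cache(tree, painting)
  n <- cache$n; p <- nrow(A); Tht <- cache$T
  eg <- eigen(A, symmetric = TRUE)
  d <- eg$values; U <- eg$vectors
  if (min(d) <= 0) stop("validation error: A not positive-definite")
  Rt <- crossprod(U, R) %*% U
  sdep <- cache$sdep
  Sigma <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) for (l in seq_len(p)) {
    ds <- d[k] + d[l]
    H <- Rt[k, l] * exp(-ds * (Tht - sdep)) * (1 - exp(-ds * sdep)) / ds
    Sigma[seq(k, by = p, length.out = n), seq(l, by = p, length.out = n)] <- H
  }
  nreg <- length(cache$regimes)
  if (is.null(cache$segtab)) {
    W <- array(1, c(n, 1, p))  # exp(-dT) + (1 - exp(-dT)) = 1
  } else {
    st <- cache$segtab
    W <- array(0, c(n, nreg, p))
    idx <- (st$regime - 1L) * n + st$tip
    for (k in seq_len(p)) {
      contrib <- exp(-d[k] * (Tht - st$t1)) - exp(-d[k] * (Tht - st$t0))
      acc <- numeric(n * nreg)
      tots <- rowsum(contrib, idx)
      acc[as.integer(rownames(tots))] <- tots
      Wk <- matrix(acc, n, nreg)
      Wk[, cache$root_regime] <- Wk[, cache$root_regime] + exp(-d[k] * Tht)
      W[, , k] <- Wk
    }
  }
  list(Sigma = Sigma, U = U, d = d, regimes = cache$regimes, W = W, T = Tht,
       n = n, p = p)
}

# Rotated tip means given rotated optima (n_regimes x p matrix).
.ou_mean_rot <- function(mod, theta_t) {
  n <- mod$n; p <- mod$p
  m <- matrix(0, n, p)
  for (ri in seq_len(nrow(theta_t))) {
    m <- m + mod$W[, ri, , drop = FALSE][, 1, ] * matrix(theta_t[ri, ], n, p, byrow = TRUE)
  }
  m
}

# Design matrix (np x nreg*p) for GLS profiling of rotated optima.
.ou_design_rot <- function(mod) {
  n <- mod$n; p <- mod$p; nr <- dim(mod$W)[2]
  B <- matrix(0, n * p, nr * p)
  for (ri in seq_len(nr)) for (k in seq_len(p)) {
    B[seq(k, by = p, length.out = n), (ri - 1) * p + k] <- mod$W[, ri, k]
  }
  B
}

# log-Cholesky (un)packing for SPD matrices; diagonal-only variant for A.
.spd_npar <- function(p, diagonal = FALSE) if (diagonal) p else p * (p + 1) / 2
.spd_unpack <- function(par, p, diagonal = FALSE) {
  if (diagonal) return(diag(exp(pmin(par, 25)), p))
  Lm <- matrix(0, p, p)
  Lm[upper.tri(Lm, diag = TRUE)] <- par
  diag(Lm) <- exp(pmin(diag(Lm), 25))
  crossprod(Lm)
}
.spd_pack <- function(M, diagonal = FALSE) {
  if (diagonal) return(log(pmax(diag(M), 1e-12)))
  Lm <- chol(M)
  diag(Lm) <- log(diag(Lm))
  Lm[upper.tri(Lm, diag = TRUE)]
}

#' Fit a multivariate trait-evolution model by maximum likelihood
#'
#' BM and EB likelihoods are profiled analytically (the GLS root mean and the
#' diffusion matrix have closed-form MLEs given the path matrix; EB adds a
#' one-dimensional search over the decay rate r). OU models optimize the
#' log-Cholesky factors of A and R by multi-start derivative-free search with
#' the optima profiled out by GLS at every evaluation. AICc uses
#' n_obs = n_taxa x n_traits.
#'
#' @inheritParams model_loglik
#' @param kind "BM", "EB", "OU1" or "OUM".
#' @param alpha_structure "spd" (full symmetric positive-definite selection
#'   matrix, default) or "diagonal".
#' @param n_restarts Perturbed restarts for OU fits (0 = single start).
#' @param seed Optional seed for restart jitter.
#' @param init Optional warm start for OU fits: list with `A` and `R`
#'   matrices (e.g. from a previous fit on a similar regime painting).
#' @return Object of class `evo_model_fit`: `kind`, `params`, `loglik`,
#'   `k_params`, `n_obs`, `aicc`, `alpha_structure`, `provenance`.
#' @export
fit_model <- function(tree, traits, kind = c("BM", "EB", "OU1", "OUM"),
                      painting = NULL, alpha_structure = c("spd", "diagonal"),
                      n_restarts = 5, seed = NULL, init = NULL) {
  kind <- match.arg(kind)
  alpha_structure <- match.arg(alpha_structure)
  X <- .align_traits(tree, traits)
  n <- nrow(X); p <- ncol(X)
  n_obs <- n * p
  if (!is.null(seed)) set.seed(seed)

  if (kind %in% c("BM", "EB")) {
    prof <- function(r) .bm_profile(.eb_C(tree, r), X)
    if (kind == "BM") {
      pf <- prof(0); r_hat <- NULL
      kpar <- p * (p + 1) / 2 + p
    } else {
      h <- tree_height(tree)
      opt <- stats::optimize(function(r) -prof(r)$loglik, c(-20 / h, 0))
      # boundary handling: r = 0 must remain admissible (BM nested in EB)
      r_hat <- if (prof(0)$loglik >= -opt$objective) 0 else opt$minimum
      pf <- prof(r_hat)
      kpar <- p * (p + 1) / 2 + p + 1
    }
    params <- list(kind = kind, R = pf$R, mu0 = pf$mu0, r = r_hat)
    return(structure(list(kind = kind, params = params, loglik = pf$loglik,
                          k_params = kpar, n_obs = n_obs,
                          aicc = aicc(pf$loglik, kpar, n_obs),
                          alpha_structure = NA_character_, provenance = NULL),
                     class = "evo_model_fit"))
  }

  if (kind == "OUM" && is.null(painting)) stop("OUM requires a regime painting")
  if (kind == "OU1") painting <- NULL
  diag_a <- alpha_structure == "diagonal"
  nA <- .spd_npar(p, diag_a); nR <- .spd_npar(p, FALSE)
  cache <- .ou_cache(tree, painting)
  h <- tree_height(tree)
  # moment inits: R from the BM fit, A from half the tree-height inverse
  bm <- .bm_profile(.eb_C(tree, 0), X)
  a0 <- 2 / h
  par0 <- if (!is.null(init)) {
    c(.spd_pack(init$A, diag_a), .spd_pack(init$R, FALSE))
  } else {
    c(.spd_pack(diag(a0, p), diag_a), .spd_pack(bm$R, FALSE))
  }
  nll <- function(par) {
    A <- .spd_unpack(par[seq_len(nA)], p, diag_a)
    R <- .spd_unpack(par[nA + seq_len(nR)], p, FALSE)
    ll <- tryCatch(.ou_profile(tree, A, R, painting, X, cache)$loglik,
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- c(list(par0), if (n_restarts > 0)
    lapply(seq_len(n_restarts), function(i)
      par0 + stats::rnorm(length(par0), 0, 0.7)))
  best <- NULL
  method <- if (length(par0) <= 12) "Nelder-Mead" else "BFGS"
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, nll, method = method,
                                 control = list(maxit = 800, reltol = 1e-8)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10)
    stop("optimizer non-convergence in fit_model(", kind, ") after all restarts")
  A <- .spd_unpack(best$par[seq_len(nA)], p, diag_a)
  R <- .spd_unpack(best$par[nA + seq_len(nR)], p, FALSE)
  of <- .ou_profile(tree, A, R, painting, X, cache)
  nreg <- nrow(of$theta)
  kpar <- nA + nR + nreg * p
  params <- list(kind = kind, R = R, A = A, theta = of$theta)
  structure(list(kind = kind, params = params, loglik = of$loglik,
                 k_params = kpar, n_obs = n_obs,
                 aicc = aicc(of$loglik, kpar, n_obs),
                 alpha_structure = alpha_structure, provenance = NULL),
            class = "evo_model_fit")
}

# Closed-form profile of multivariate BM/EB given the path matrix C.
.bm_profile <- function(C, X) {
  n <- nrow(X); p <- ncol(X)
  L <- chol(C)
  W <- backsolve(L, X, transpose = TRUE)       # L^-T X
  one <- backsolve(L, rep(1, n), transpose = TRUE)
  mu0 <- drop(crossprod(one, W)) / sum(one^2)
  Wc <- W - outer(one, mu0)
  R <- crossprod(Wc) / n
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    return(list(loglik = -Inf, R = R, mu0 = mu0))
  ld_R <- sum(log(eigen(R, symmetric = TRUE, only.values = TRUE)$values))
  loglik <- -0.5 * n * p * log(2 * pi) - 0.5 * n * ld_R -
    p * sum(log(diag(L))) - 0.5 * n * p
  list(loglik = loglik, R = R, mu0 = mu0)
}

# OU likelihood with optima profiled by GLS (rotated basis).
.ou_profile <- function(tree, A, R, painting, X, cache = NULL) {
  mod <- .ou_rotated(tree, A, R, painting, cache)
  p <- mod$p
  L <- tryCatch(chol(mod$Sigma), error = function(e) NULL)
  if (is.null(L)) stop("singular OU covariance")
  B <- .ou_design_rot(mod)
  y <- as.vector(t(X %*% mod$U))
  Bw <- backsolve(L, B, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qrB <- qr(Bw)
  if (qrB$rank < ncol(Bw)) stop("singular optimum design (regime barely present)")
  th <- qr.coef(qrB, yw)
  res <- yw - Bw %*% th
  loglik <- -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(res^2))
  # th is stacked regime-major, p rotated entries per regime
  theta_t <- matrix(th, ncol = p, byrow = TRUE, dimnames = list(mod$regimes, NULL))
  theta <- theta_t %*% t(mod$U)
  colnames(theta) <- colnames(X)
  list(loglik = loglik, theta = theta, mod = mod)
}

#' Simulate trait matrices from a fitted or specified model
#'
#' Exact Gaussian simulation from the model's mean vector and covariance
#' matrix (no branch-wise discretization). A zero diffusion matrix is allowed
#' as a degenerate boundary: every tip then equals its model mean.
#'
#' @inheritParams model_loglik
#' @param n_sims Number of replicate trait matrices.
#' @param seed Optional seed.
#' @return List of taxa x dimensions matrices.
#' @export
simulate_traits <- function(tree, params, painting = NULL, n_sims = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kind <- match.arg(params$kind, c("BM", "EB", "OU1", "OUM"))
  n <- length(tree$tip.label)
  R <- params$R
  p <- nrow(R)
  zeroR <- all(R == 0)
  if (!zeroR) .check_spd(R, "R")
  if (kind %in% c("BM", "EB")) {
    C <- .eb_C(tree, if (kind == "EB") params$r else 0)
    m <- matrix(params$mu0, n, p, byrow = TRUE)
    Sigma <- kronecker(C, R)
    rot <- NULL
  } else {
    .check_spd(params$A, "A")
    if (kind == "OU1") painting <- NULL  # single optimum: painting irrelevant
    mod <- .ou_rotated(tree, params$A, if (zeroR) diag(1e-8, p) else R, painting)
    theta_t <- if (kind == "OU1") matrix(drop(crossprod(mod$U, as.numeric(params$theta))), 1, p)
               else params$theta[mod$regimes, , drop = FALSE] %*% mod$U
    m <- .ou_mean_rot(mod, theta_t)
    Sigma <- if (zeroR) matrix(0, n * p, n * p) else mod$Sigma
    rot <- mod$U
  }
  mvec <- as.vector(t(m))
  Lr <- if (zeroR) NULL else chol(Sigma + diag(1e-12, nrow(Sigma)))
  tips <- tree$tip.label
  lapply(seq_len(n_sims), function(i) {
    y <- if (is.null(Lr)) mvec else mvec + drop(crossprod(Lr, stats::rnorm(length(mvec))))
    Xi <- matrix(y, n, p, byrow = TRUE)
    if (!is.null(rot)) Xi <- Xi %*% t(rot)
    rownames(Xi) <- tips
    colnames(Xi) <- paste0("Dim", seq_len(p))
    Xi
  })
}

#' @rdname simulate_traits
#' @param fit An `evo_model_fit`.
#' @export
simulate_from_fit <- function(tree, fit, painting = NULL, n_sims = 1, seed = NULL) {
  simulate_traits(tree, fit$params, painting = painting, n_sims = n_sims, seed = seed)
}

#' Akaike weights across a set of model fits
#'
#' @param fits List of `evo_model_fit` objects fitted to identical data, or a
#'   bare numeric vector of AICc values.
#' @return Data frame (model, loglik, k_params, aicc, delta, weight) sorted
#'   by AICc; weights sum to 1.
#' @export
akaike_weights <- function(fits) {
  if (is.numeric(fits)) {
    a <- fits
    tab <- data.frame(model = names(a) %||% paste0("m", seq_along(a)), aicc = a,
                      stringsAsFactors = FALSE)
  } else {
    if (length(fits) < 2) stop("need >= 2 fits")
    nobs <- vapply(fits, `[[`, 0, "n_obs")
    if (length(unique(nobs)) != 1) stop("fits are on mismatched data (n_obs differ)")
    tab <- data.frame(model = names(fits) %||% vapply(fits, `[[`, "", "kind"),
                      loglik = vapply(fits, `[[`, 0, "loglik"),
                      k_params = vapply(fits, `[[`, 0, "k_params"),
                      aicc = vapply(fits, `[[`, 0, "aicc"),
                      stringsAsFactors = FALSE)
  }
  tab$delta <- tab$aicc - min(tab$aicc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  tab[order(tab$aicc), , drop = FALSE]
}

#' Fit OUM models over a sample of stochastic habitat maps
#'
#' Mirrors the regime-uncertainty protocol: take a random subsample of the
#' stochastic maps, restrict each to the analysis tree, fit one OUM model per
#' map, and carry the best few (by AICc) into the final model comparison.
#'
#' @param tree Analysis tree (possibly pruned to taxa with traits).
#' @param traits Trait matrix.
#' @param maps List of `stochastic_map`s (sampled on `full_tree` if given).
#' @param full_tree Tree the maps were sampled on, when different from
#'   `tree`.
#' @param n_sample Number of maps to fit (default 100).
#' @param keep_best How many best-AICc fits to return (default 3).
#' @param seed Seed for the map subsample.
#' @param ... Passed to [fit_model()].
#' @return List of `evo_model_fit`s (length `keep_best`), each with
#'   `provenance` = index of its source map and `painting` attached.
#' @export
fit_oum_over_maps <- function(tree, traits, maps, full_tree = NULL,
                              n_sample = 100, keep_best = 3, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- if (length(maps) > n_sample) sort(sample.int(length(maps), n_sample))
         else seq_along(maps)
  fits <- vector("list", length(idx))
  warm <- NULL
  for (i in seq_along(idx)) {
    map <- maps[[idx[i]]]
    painting <- if (is.null(full_tree) || identical(full_tree$tip.label, tree$tip.label))
      as_regime_painting(map) else prune_map_to(map, full_tree, tree)
    args <- list(tree = tree, traits = traits, kind = "OUM",
                 painting = painting, ...)
    if (!is.null(warm)) {
      # warm-start subsequent maps from the first converged fit: paintings
      # differ only in regime layout, so A and R land near their optima
      args$n_restarts <- 0
      args$init <- warm
    }
    ft <- tryCatch(do.call(fit_model, args), error = function(e) NULL)
    if (!is.null(ft)) {
      if (is.null(warm)) warm <- list(A = ft$params$A, R = ft$params$R)
      ft$provenance <- idx[i]
      ft$painting <- painting
    }
    fits[[i]] <- ft
  }
  fits <- fits[!vapply(fits, is.null, TRUE)]
  if (!length(fits)) stop("no OUM fit converged on any sampled map")
  ord <- order(vapply(fits, `[[`, 0, "aicc"))
  fits[ord[seq_len(min(keep_best, length(fits)))]]
}

#' Simulation-envelope validation of a fitted model
#'
#' Simulates `n_sims` datasets from the fitted model and flags, per taxon and
#' dimension, whether the observed value lies within the simulated
#' mean +/- 2 SD.
#'
#' @inheritParams model_loglik
#' @param fit `evo_model_fit` (with `$painting` for OUM, or pass `painting`).
#' @param n_sims Number of simulations (>= 2).
#' @param seed Optional seed.
#' @param dims Dimensions to check (default: all).
#' @return List with `table` (taxon, dim, observed, sim_mean, sim_sd,
#'   within_2sd), `pass_fraction`, `n_sims`.
#' @export
envelope_check <- function(tree, traits, fit, n_sims = 1000, seed = NULL,
                           painting = NULL, dims = NULL) {
  if (n_sims < 2) stop("n_sims must be >= 2")
  X <- .align_traits(tree, traits)
  painting <- painting %||% fit$painting
  sims <- simulate_from_fit(tree, fit, painting = painting, n_sims = n_sims,
                            seed = seed)
  dims <- dims %||% seq_len(ncol(X))
  arr <- array(unlist(sims), c(nrow(X), ncol(X), n_sims))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  rows <- expand.grid(taxon = tree$tip.label, dim = dims, stringsAsFactors = FALSE)
  obs <- X[cbind(match(rows$taxon, tree$tip.label), rows$dim)]
  sm <- mu[cbind(match(rows$taxon, tree$tip.label), rows$dim)]
  ss <- sdv[cbind(match(rows$taxon, tree$tip.label), rows$dim)]
  within <- ifelse(ss == 0, obs == sm, abs(obs - sm) <= 2 * ss)
  tab <- data.frame(rows, observed = obs, sim_mean = sm, sim_sd = ss,
                    within_2sd = within)
  list(table = tab, pass_fraction = mean(within), n_sims = n_sims)
}
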