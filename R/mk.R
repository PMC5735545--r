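#' The five-state larval habitat alphabet
#'
#' Ordered state set used for the habitat character: container, rock pool,
#' crab hole, salt pool, ground pool. State indices are stable across a run.
#'
#' @return Character vector of length 5.
#' @export
habitat_states <- function() {
  c("container", "rock_pool", "crab_hole", "salt_pool", "ground_pool")
}

#' Build an Mk generator matrix under a rate-model constraint
#'
#' @param rates Numeric vector of free rates: length 1 (ER), k(k-1)/2 (SYM,
#'   filling the upper triangle row-wise and mirrored), or k(k-1) (ARD,
#'   filling off-diagonals row-wise).
#' @param kind One of "ER", "SYM", "ARD".
#' @param k Number of states.
#' @param states Optional state names for dimnames.
#' @return k x k generator with non-negative off-diagonals and zero row sums.
#' @export
build_rate_matrix <- function(rates, kind = c("ER", "SYM", "ARD"), k, states = NULL) {
  kind <- match.arg(kind)
  np <- mk_n_params(kind, k)
  if (length(rates) != np) stop("expected ", np, " rates for ", kind, " with k=", k)
  if (any(rates < 0)) stop("validation error: negative rate")
  Q <- matrix(0, k, k)
  if (kind == "ER") {
    Q[row(Q) != col(Q)] <- rates[1]
  } else if (kind == "SYM") {
    idx <- which(upper.tri(Q))
    # fill row-wise for stable parameter order
    ut <- which(upper.tri(Q), arr.ind = TRUE)
    ord <- order(ut[, 1], ut[, 2])
    Q[idx[ord]] <- rates
    Q <- Q + t(Q)
  } else {
    off <- which(row(Q) != col(Q), arr.ind = TRUE)
    ord <- order(off[, 1], off[, 2])
    Q[off[ord, , drop = FALSE]] <- rates
  }
  diag(Q) <- -rowSums(Q)
  if (!is.null(states)) dimnames(Q) <- list(states, states)
  Q
}

#' @rdname build_rate_matrix
#' @export
mk_n_params <- function(kind = c("ER", "SYM", "ARD"), k) {
  kind <- match.arg(kind)
  switch(kind, ER = 1L, SYM = as.integer(k * (k - 1) / 2), ARD = as.integer(k * (k - 1)))
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be square")
  off <- Q[row(Q) != col(Q)]
  if (any(off < -1e-12)) stop("validation error: negative off-diagonal rate in Q")
  if (any(abs(rowSums(Q)) > 1e-10)) stop("validation error: Q row sums must be 0")
  invisible(Q)
}

#' Build tip state priors from a habitat table
#'
#' Multi-habitat taxa receive equal mass on each occupied state; taxa with
#' unknown habitat receive a uniform vector.
#'
#' @param habitats Named character vector (or data.frame with columns `taxon`,
#'   `habitat`), habitat entries as semicolon-separated state lists, `NA` or
#'   `""` meaning unknown.
#' @param states State alphabet (default [habitat_states()]).
#' @return Matrix taxa x states of tip prior probabilities, rows sum to 1.
#' @export
make_tip_priors <- function(habitats, states = habitat_states()) {
  if (is.data.frame(habitats)) {
    habitats <- stats::setNames(as.character(habitats$habitat), habitats$taxon)
  }
  names(habitats) <- normalize_labels(names(habitats))
  k <- length(states)
  out <- matrix(0, length(habitats), k, dimnames = list(names(habitats), states))
  for (i in seq_along(habitats)) {
    h <- habitats[i]
    if (is.na(h) || h == "") {
      out[i, ] <- 1 / k
    } else {
      occ <- normalize_states(strsplit(h, ";")[[1]], states)
      out[i, occ] <- 1 / length(occ)
    }
  }
  out
}

normalize_states <- function(x, states) {
  x <- gsub("^\\s+|\\s+$", "", tolower(x))
  x <- gsub("[ -]", "_", x)
  bad <- setdiff(x, states)
  if (length(bad)) stop("unknown habitat state(s): ", paste(bad, collapse = ", "))
  x
}

# Transition probability matrices exp(Q * t) for a vector of branch lengths.
# Eigendecomposition fast path (one decomposition, all branches); falls back
# to scaling-and-squaring (Matrix::expm) when the eigenbasis is
# ill-conditioned. Returns k x k x length(t) array.
transition_probs <- function(Q, tvec) {
  k <- nrow(Q)
  out <- array(0, c(k, k, length(tvec)))
  eg <- eigen(Q)
  Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
  if (!is.null(Vi)) {
    for (i in seq_along(tvec)) {
      P <- Re(eg$vectors %*% (exp(eg$values * tvec[i]) * Vi))
      out[, , i] <- P
    }
    # sanity: rows of a probability matrix
    if (max(abs(apply(out, 3, rowSums) - 1)) < 1e-8 && min(out) > -1e-8) {
      out[out < 0] <- 0
      return(out)
    }
  }
  for (i in seq_along(tvec)) {
    out[, , i] <- as.matrix(Matrix::expm(Q * tvec[i]))
  }
  out
}

# Internal: align tip prior matrix to tree tips, with validation.
.align_tips <- function(tree, tip_priors, k = NULL) {
  missing <- setdiff(tree$tip.label, rownames(tip_priors))
  if (length(missing))
    stop("tips missing from data: ", paste(missing, collapse = ", "))
  tp <- tip_priors[tree$tip.label, , drop = FALSE]
  if (any(tp < 0) || any(abs(rowSums(tp) - 1) > 1e-8))
    stop("validation error: tip priors must be non-negative and sum to 1")
  tp
}

# Pruning pass: conditional likelihoods of data below each node given its
# state, with per-node rescaling. Returns list(partials, logscale, Parr).
.mk_prune <- function(tree, tp, Q) {
  k <- ncol(tp)
  n <- length(tree$tip.label); m <- tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  Parr <- transition_probs(Q, po$edge.length)
  L <- matrix(0, n + m, k)
  L[seq_len(n), ] <- tp
  prod_init <- rep(1, k)
  logscale <- 0
  # messages: accumulate child contributions into parent rows
  acc <- matrix(1, n + m, k)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    Lc <- if (ch <= n) L[ch, ] else {
      v <- acc[ch, ]
      s <- sum(v)
      logscale <- logscale + log(s)
      v <- v / s
      L[ch, ] <- v
      v
    }
    acc[par, ] <- acc[par, ] * as.vector(Parr[, , e] %*% Lc)
  }
  root <- n + 1L
  s <- sum(acc[root, ])
  logscale <- logscale + log(s)
  L[root, ] <- acc[root, ] / s
  list(L = L, logscale = logscale, po = po, Parr = Parr)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tree `phylo` with branch lengths.
#' @param tip_priors Matrix taxa x states from [make_tip_priors()].
#' @param Q Generator matrix.
#' @param root_prior Probability vector over states (default flat).
#' @return Log-likelihood.
#' @export
mk_loglik <- function(tree, tip_priors, Q, root_prior = NULL) {
  validate_rate_matrix(Q)
  tp <- .align_tips(tree, tip_priors)
  if (ncol(tp) != nrow(Q)) stop("tip priors and Q disagree on number of states")
  k <- nrow(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  pr <- .mk_prune(tree, tp, Q)
  root <- length(tree$tip.label) + 1L
  log(sum(root_prior * pr$L[root, ])) + pr$logscale
}

#' Fit an Mk rate model by maximum likelihood
#'
#' Rates are optimized in log space with bounded L-BFGS-B and multiple random
#' restarts. AICc uses n = number of tips.
#'
#' @inheritParams mk_loglik
#' @param kind Rate constraint: "ER", "SYM" or "ARD".
#' @param n_restarts Random restarts beyond the moment-based start.
#' @param seed Optional seed controlling restart jitter.
#' @return List with `Q`, `rates`, `kind`, `loglik`, `k_params`, `aicc`.
#' @export
fit_mk <- function(tree, tip_priors, kind = c("ER", "SYM", "ARD"),
                   root_prior = NULL, n_restarts = 5, seed = NULL) {
  kind <- match.arg(kind)
  tp <- .align_tips(tree, tip_priors)
  k <- ncol(tp)
  np <- mk_n_params(kind, k)
  if (!is.null(seed)) set.seed(seed)
  n_states_obs <- sum(colSums(tp) > 0)
  if (n_states_obs < 2) {
    # single observed state: rate MLE is 0
    Q <- build_rate_matrix(rep(1e-9, np), kind, k, colnames(tp))
    ll <- mk_loglik(tree, tp, Q, root_prior)
    return(list(Q = Q, rates = rep(1e-9, np), kind = kind, loglik = ll,
                k_params = np, aicc = aicc(ll, np, length(tree$tip.label))))
  }
  lb <- log(1e-9); ub <- log(1e3)
  q0 <- log(max(n_states_obs / sum(tree$edge.length), 1.01e-9))
  nll <- function(lr) {
    Q <- build_rate_matrix(exp(lr), kind, k, colnames(tp))
    ll <- tryCatch(mk_loglik(tree, tp, Q, root_prior), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- c(list(rep(q0, np)),
              lapply(seq_len(n_restarts), function(i) rep(q0, np) + stats::rnorm(np, 0, 1.5)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(pmin(pmax(s, lb), ub), nll, method = "L-BFGS-B",
                   lower = lb, upper = ub, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("optimizer non-convergence in fit_mk after all restarts")
  rates <- exp(best$par)
  Q <- build_rate_matrix(rates, kind, k, colnames(tp))
  ll <- -best$value
  list(Q = Q, rates = rates, kind = kind, loglik = ll, k_params = np,
       aicc = aicc(ll, np, length(tree$tip.label)))
}

#' Compare Mk rate models by AICc weight
#'
#' @inheritParams fit_mk
#' @param kinds Models to compare.
#' @return Data frame (kind, loglik, k_params, aicc, delta, weight) sorted by
#'   AICc, plus attribute `fits` with the full fit objects.
#' @export
compare_mk_models <- function(tree, tip_priors, kinds = c("ER", "SYM", "ARD"),
                              root_prior = NULL, n_restarts = 5, seed = NULL) {
  k <- ncol(tip_priors)
  n <- length(tree$tip.label)
  ok <- vapply(kinds, function(kk) mk_n_params(kk, k) + 1 < n, TRUE)
  if (!all(ok)) {
    warning("dropping rate model(s) with too many parameters for ", n,
            " tips: ", paste(kinds[!ok], collapse = ", "))
    kinds <- kinds[ok]
  }
  if (!length(kinds)) stop("no admissible rate model for this tip count")
  fits <- lapply(kinds, function(kk)
    fit_mk(tree, tip_priors, kk, root_prior, n_restarts, seed))
  names(fits) <- kinds
  a <- vapply(fits, `[[`, 0, "aicc")
  d <- a - min(a)
  w <- exp(-d / 2); w <- w / sum(w)
  tab <- data.frame(kind = kinds, loglik = vapply(fits, `[[`, 0, "loglik"),
                    k_params = vapply(fits, `[[`, 0L, "k_params"),
                    aicc = a, delta = d, weight = w, stringsAsFactors = FALSE)
  tab <- tab[order(tab$aicc), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Marginal ancestral-state reconstruction under an Mk model
#'
#' Combines the upward (pruning) and downward passes to give, for every
#' internal node, the posterior probability of each state integrating over
#' all other nodes.
#'
#' @inheritParams mk_loglik
#' @return List with `node_probs` (matrix internal nodes x states; rownames
#'   are ape node ids), `loglik`, `Q`.
#' @export
marginal_asr <- function(tree, tip_priors, Q, root_prior = NULL) {
  validate_rate_matrix(Q)
  tp <- .align_tips(tree, tip_priors)
  k <- nrow(Q)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  pr <- .mk_prune(tree, tp, Q)
  n <- length(tree$tip.label); m <- tree$Nnode
  root <- n + 1L
  po <- pr$po; Parr <- pr$Parr; L <- pr$L
  # messages child -> parent, cached for sibling products
  msg <- matrix(0, n + m, k)  # msg[ch,] = P_e %*% L_ch
  for (e in seq_len(nrow(po$edge))) {
    msg[po$edge[e, 2], ] <- as.vector(Parr[, , e] %*% L[po$edge[e, 2], ])
  }
  U <- matrix(0, n + m, k)
  U[root, ] <- root_prior
  # preorder: reverse postorder edge sweep
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sibs <- po$edge[po$edge[, 1] == par, 2]
    F_par <- U[par, ]
    for (b in setdiff(sibs, ch)) F_par <- F_par * msg[b, ]
    u <- as.vector(F_par %*% Parr[, , e])  # sum_s F(s) P(s, s')
    s <- sum(u)
    U[ch, ] <- if (s > 0) u / s else u
  }
  post <- U * L
  post <- post / rowSums(post)
  node_probs <- post[(n + 1):(n + m), , drop = FALSE]
  rownames(node_probs) <- as.character((n + 1):(n + m))
  colnames(node_probs) <- colnames(tp)
  list(node_probs = node_probs, loglik = log(sum(root_prior * L[root, ])) + pr$logscale,
       Q = Q)
}

#' Find the most recent common ancestor node of a set of tips
#'
#' Convenience for reading reconstructions at named clades (e.g. the Aedini
#' root or the ancestor of all *Aedes* taxa).
#'
#' @param tree `phylo`.
#' @param tips Character vector of tip labels (>= 2).
#' @return ape node id (integer).
#' @export
mrca_node <- function(tree, tips) {
  tips <- normalize_labels(tips)
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown)) stop("unknown tips: ", paste(unknown, collapse = ", "))
  if (length(tips) < 2) stop("need >= 2 tips")
  ape::getMRCA(tree, tips)
}
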