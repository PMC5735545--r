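#' Blomberg's K with permutation test
#'
#' K compares the observed ratio of tip-level mean squared deviation from the
#' phylogenetic (GLS) mean (MSE0) to the GLS mean squared error under the
#' tree covariance (MSE), standardized by the Brownian-motion expectation of
#' that ratio, so K = 1 is the BM expectation, K > 1 indicates variance
#' concentrated among clades. Significance by shuffling tip labels.
#'
#' @param tree Ultrametric `phylo`.
#' @param trait Named numeric vector (or 1-column matrix) of tip values.
#' @param n_perm Number of label permutations.
#' @param seed Optional seed.
#' @return List `K`, `p` (add-one proportion of permuted K >= observed),
#'   `n_perm`, `obs_ratio`, `expected_ratio`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000, seed = NULL) {
  if (is.matrix(trait) || is.data.frame(trait)) {
    nm <- rownames(trait); trait <- as.numeric(trait[, 1]); names(trait) <- nm
  }
  names(trait) <- normalize_labels(names(trait))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) stop("taxa missing trait: ", paste(missing, collapse = ", "))
  x <- trait[tree$tip.label]
  if (stats::sd(x) == 0) stop("degenerate statistic: constant trait")
  n <- length(x)
  C <- ape::vcv(tree)
  Ci <- solve(C)
  one <- rep(1, n)
  denom1 <- drop(one %*% Ci %*% one)
  expected <- (sum(diag(C)) - n / denom1) / (n - 1)
  k_of <- function(v) {
    a <- drop(one %*% Ci %*% v) / denom1
    dv <- v - a
    mse0 <- sum(dv^2) / (n - 1)
    mse <- drop(dv %*% Ci %*% dv) / (n - 1)
    (mse0 / mse) / expected
  }
  K <- k_of(x)
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) k_of(sample(x)), 0)
  list(K = K, p = p_add_one(perm, K), n_perm = n_perm,
       obs_ratio = K * expected, expected_ratio = expected)
}

# One-way MANOVA sums-of-squares statistics: Wilks' Lambda and its Rao F
# approximation. groups: factor aligned with rows of X.
wilks_stat <- function(X, groups) {
  X <- as.matrix(X)
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups); n <- nrow(X); p <- ncol(X)
  if (g < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("every group needs >= 2 taxa")
  gm <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  for (lv in levels(groups)) {
    Xi <- X[groups == lv, , drop = FALSE]
    mi <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, mi))
    B <- B + nrow(Xi) * tcrossprod(mi - gm)
  }
  dW <- det(W); dT <- det(W + B)
  if (dW <= 0 || dT <= 0)
    stop("singular within-group covariance; use fewer dimensions")
  lambda <- dW / dT
  # Rao's F approximation
  q <- g - 1
  s <- sqrt(ifelse(p^2 + q^2 - 5 > 0, (p^2 * q^2 - 4) / (p^2 + q^2 - 5), 1))
  df1 <- p * q
  df2 <- s * ((n - g) - (p - q + 1) / 2) - (p * q - 2) / 2
  lam_s <- lambda^(1 / s)
  Fstat <- (1 - lam_s) / lam_s * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2)
}

#' Phylogenetic MANOVA with model-based simulated nulls
#'
#' The observed statistic is the ordinary one-way MANOVA Wilks' Lambda (via
#' its F approximation) of the traits on the habitat groups; the phylogeny
#' enters through the null distribution, obtained by simulating trait
#' matrices on the tree under a fitted evolutionary model and recomputing the
#' statistic per simulation. For bare model kinds (BM/EB/OU1) the null
#' parameters are first fitted to the observed traits ignoring groups; a
#' user-supplied fit (e.g. the best OUM model, which retains habitat-linked
#' optima) is used as-is, turning the test into a plausibility check of that
#' model.
#'
#' @param tree Ultrametric `phylo`.
#' @param traits Taxa x dimensions matrix.
#' @param groups Named character vector taxon -> habitat (single state).
#' @param null Model kind ("BM", "EB", "OU1") or an `evo_model_fit`.
#' @param n_sims Number of null simulations.
#' @param seed Optional seed.
#' @param painting Regime painting, if `null` is an OUM fit without one
#'   attached.
#' @return List `lambda`, `F`, `df1`, `df2`, `p` (add-one proportion of null
#'   F >= observed), `null_kind`, `n_sims`, `null_F_summary`.
#' @export
phylo_manova <- function(tree, traits, groups, null = "BM", n_sims = 1000,
                         seed = NULL, painting = NULL) {
  X <- .align_traits(tree, traits)
  names(groups) <- normalize_labels(names(groups))
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing)) stop("taxa missing groups: ", paste(missing, collapse = ", "))
  g <- factor(groups[tree$tip.label])
  obs <- wilks_stat(X, g)
  if (inherits(null, "evo_model_fit")) {
    fit <- null
    null_kind <- paste0("fit:", fit$kind)
    painting <- painting %||% fit$painting
  } else {
    null_kind <- match.arg(null, c("BM", "EB", "OU1"))
    fit <- fit_model(tree, X, null_kind, n_restarts = 2)
  }
  sims <- simulate_from_fit(tree, fit, painting = painting, n_sims = n_sims,
                            seed = seed)
  nullF <- vapply(sims, function(S) {
    tryCatch(wilks_stat(S, g)$F, error = function(e) NA_real_)
  }, 0)
  nullF <- nullF[is.finite(nullF)]
  list(lambda = obs$lambda, F = obs$F, df1 = obs$df1, df2 = obs$df2,
       p = p_add_one(nullF, obs$F), null_kind = null_kind,
       n_sims = length(nullF),
       null_F_summary = stats::quantile(nullF, c(0.05, 0.5, 0.95)))
}

#' Wheatsheaf index of convergence strength
#'
#' Measures how much more tightly a focal group (e.g. container specialists)
#' clusters in phenotype space than the sample as a whole, discounting
#' similarity attributable to shared ancestry. Traits are z-scored per
#' dimension; Euclidean phenotypic distances are penalized multiplicatively
#' by phylogenetic relatedness, `q_ij = E_ij * (1 + rho_ij)` with `rho_ij`
#' the shared root-to-MRCA fraction of the tree height, so phenotypic
#' similarity between close relatives is down-weighted. Then
#' `w = mean(q, all pairs) / mean(q, focal pairs)`; w = 1 exactly when the
#' focal group is the whole sample, and w >> 1 with small p indicates strong
#' convergence (or conservation) in the focal group. Significance by
#' bootstrap: random focal sets of the same size (add-one proportion of
#' bootstrap w >= observed).
#'
#' @param tree Ultrametric `phylo`.
#' @param traits Taxa x dimensions matrix (use one column for a
#'   per-dimension index).
#' @param focal Character vector of focal taxa (2 <= |focal| <= n).
#' @param n_boot Bootstrap replicates.
#' @param seed Optional seed.
#' @return List `w`, `p`, `n_boot`, `focal_n`.
#' @export
wheatsheaf <- function(tree, traits, focal, n_boot = 1000, seed = NULL) {
  X <- .align_traits(tree, traits)
  focal <- normalize_labels(focal)
  absent <- setdiff(focal, tree$tip.label)
  if (length(absent)) stop("focal taxa absent from tree: ", paste(absent, collapse = ", "))
  if (length(focal) < 2) stop("need >= 2 focal taxa")
  n <- nrow(X)
  Z <- scale(X)
  E <- as.matrix(stats::dist(Z))
  C <- ape::vcv(tree)
  rho <- C / max(diag(C))          # shared-path fraction, in [0, 1]
  Q <- E * (1 + rho)
  up <- upper.tri(Q)
  w_of <- function(taxa) {
    idx <- match(taxa, tree$tip.label)
    sub <- Q[idx, idx, drop = FALSE]
    mean(Q[up]) / mean(sub[upper.tri(sub)])
  }
  w <- w_of(focal)
  if (length(focal) == n) {
    return(list(w = 1, p = 1, n_boot = 0, focal_n = n))
  }
  if (!is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i)
    w_of(sample(tree$tip.label, length(focal))), 0)
  list(w = w, p = p_add_one(boot, w), n_boot = n_boot, focal_n = length(focal))
}
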