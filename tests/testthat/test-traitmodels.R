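star_tree <- function(n, len = 2) {
  tr <- ape::stree(n, "star")
  tr$edge.length <- rep(len, n)
  tr
}

test_that("BM on a star tree reduces to the iid Gaussian closed form", {
  set.seed(5)
  n <- 30; Tlen <- 2
  tr <- star_tree(n, Tlen)
  x <- matrix(rnorm(n, 3, 1.5), dimnames = list(tr$tip.label, "Dim1"))
  f <- fit_model(tr, x, "BM")
  sig2 <- sum((x - mean(x))^2) / (n * Tlen)
  expect_equal(unname(f$params$R[1, 1]), sig2, tolerance = 1e-8)
  expect_equal(unname(f$params$mu0), mean(x), tolerance = 1e-8)
  ll_iid <- sum(stats::dnorm(x, mean(x), sqrt(sig2 * Tlen), log = TRUE))
  expect_equal(f$loglik, ll_iid, tolerance = 1e-8)
})

test_that("model likelihoods equal the brute-force covariance oracle", {
  ds <- simulate_dataset(n_taxa = 5, seed = 11, n_chars = 5, rate = 0.8)
  tr <- ds$tree
  pa <- as_regime_painting(ds$history)
  set.seed(9)
  p <- 2
  R <- matrix(c(0.6, 0.2, 0.2, 0.5), 2)
  A <- matrix(c(1.5, 0.4, 0.4, 0.9), 2)
  X <- matrix(rnorm(5 * p), 5, p, dimnames = list(tr$tip.label, NULL))

  bm <- list(kind = "BM", R = R, mu0 = c(0.3, -0.2))
  expect_equal(model_loglik(tr, X, bm),
               oracle_model_loglik(tr, X, bm), tolerance = 1e-6)

  eb <- list(kind = "EB", R = R, mu0 = c(0.3, -0.2), r = -1.2)
  expect_equal(model_loglik(tr, X, eb),
               oracle_model_loglik(tr, X, eb), tolerance = 1e-6)

  ou1 <- list(kind = "OU1", R = R, A = A, theta = c(0.5, -0.5))
  expect_equal(model_loglik(tr, X, ou1),
               oracle_model_loglik(tr, X, ou1), tolerance = 1e-5)

  regs <- pa$regimes
  theta <- matrix(rnorm(length(regs) * p), length(regs), p,
                  dimnames = list(regs, NULL))
  oum <- list(kind = "OUM", R = R, A = A, theta = theta)
  expect_equal(model_loglik(tr, X, oum, painting = pa),
               oracle_model_loglik(tr, X, oum, painting = pa), tolerance = 1e-5)
})

test_that("EB with r = 0 reproduces BM exactly and nests above it", {
  ds <- simulate_dataset(n_taxa = 20, seed = 3, n_chars = 10)
  X <- run_mca(ds$morphology, 2)$traits
  bm <- fit_model(ds$tree, X, "BM")
  eb0 <- model_loglik(ds$tree, X,
                      list(kind = "EB", R = bm$params$R, mu0 = bm$params$mu0,
                           r = 0))
  expect_equal(eb0, bm$loglik, tolerance = 1e-10)
  eb <- fit_model(ds$tree, X, "EB")
  expect_gte(eb$loglik, bm$loglik - 1e-8)
})

test_that("zero diffusion collapses simulations onto the model mean", {
  tr <- random_tree(6, seed = 4)
  params <- list(kind = "BM", R = matrix(0, 2, 2), mu0 = c(1, -1))
  sims <- simulate_traits(tr, params, n_sims = 3, seed = 1)
  for (s in sims) {
    expect_equal(unname(s), matrix(c(1, -1), 6, 2, byrow = TRUE))
  }
})

test_that("BM simulation matches the path-length covariance (moments)", {
  tr <- random_tree(6, seed = 8)
  sig2 <- 0.7
  params <- list(kind = "BM", R = matrix(sig2, 1, 1), mu0 = 0)
  sims <- simulate_traits(tr, params, n_sims = 5000, seed = 2)
  M <- do.call(cbind, lapply(sims, function(s) s[, 1]))
  emp <- tcrossprod(M - rowMeans(M)) / (ncol(M) - 1)
  theo <- sig2 * ape::vcv(tr)
  # elementwise within 3 MC SE (Wishart variance of a covariance entry)
  nsim <- ncol(M)
  se <- sqrt((outer(diag(theo), diag(theo)) + theo^2) / nsim)
  expect_true(all(abs(emp - theo) < 3.5 * se + 1e-8))
})

test_that("strong selection pulls tip means to their regime optima", {
  ds <- simulate_dataset(n_taxa = 12, seed = 21, rate = 0.3)
  pa <- as_regime_painting(ds$history)
  regs <- pa$regimes
  theta <- matrix(seq_len(length(regs) * 2), length(regs), 2,
                  dimnames = list(regs, NULL))
  params <- list(kind = "OUM", R = diag(1e-4, 2), A = diag(50, 2),
                 theta = theta)
  sims <- simulate_traits(ds$tree, params, painting = pa, n_sims = 200,
                          seed = 3)
  avg <- Reduce(`+`, sims) / length(sims)
  tipreg <- ds$tip_states[ds$tree$tip.label]
  # the limit applies to tips that spent >> 1/alpha in their final regime
  eoc <- match(seq_len(12), ds$tree$edge[, 2])
  final_seg <- vapply(eoc, function(e) tail(pa$edge_maps[[e]], 1), 0)
  for (i in which(final_seg > 0.15)) {
    expect_lt(max(abs(avg[i, ] - theta[tipreg[i], ])), 0.06)
  }
  expect_gt(sum(final_seg > 0.15), 3)  # the check actually bites
})

test_that("Akaike weights normalize, tie evenly, and are translation-invariant", {
  w <- akaike_weights(c(m1 = 10, m2 = 10))
  expect_equal(w$weight, c(0.5, 0.5))
  set.seed(2)
  a <- runif(5, -300, -100)
  w1 <- akaike_weights(a)
  expect_equal(sum(w1$weight), 1, tolerance = 1e-12)
  w2 <- akaike_weights(a + 57.3)
  expect_equal(w1$weight, w2$weight, tolerance = 1e-10)
  expect_equal(w1$delta, w2$delta, tolerance = 1e-10)
  expect_error(akaike_weights(list()), "2 fits")
})

test_that("fits on mismatched data are rejected by the weight table", {
  d1 <- simulate_dataset(n_taxa = 10, seed = 1, n_chars = 8)
  d2 <- simulate_dataset(n_taxa = 12, seed = 2, n_chars = 8)
  X1 <- run_mca(d1$morphology, 2)$traits
  X2 <- run_mca(d2$morphology, 2)$traits
  f1 <- fit_model(d1$tree, X1, "BM")
  f2 <- fit_model(d2$tree, X2, "BM")
  expect_error(akaike_weights(list(f1, f2)), "mismatched")
})

test_that("envelope flags exact equality when SD is zero and catches outliers", {
  tr <- random_tree(8, seed = 6)
  fit <- structure(list(kind = "BM", n_obs = 8,
                        params = list(kind = "BM", R = matrix(0, 1, 1), mu0 = 2)),
                   class = "evo_model_fit")
  X <- matrix(2, 8, 1, dimnames = list(tr$tip.label, "Dim1"))
  X[1, 1] <- 2 + 1e-9  # avoid zero-variance rejection
  X2 <- X; X2[3, 1] <- 5
  env <- envelope_check(tr, X2, fit, n_sims = 5, seed = 1)
  expect_equal(sum(!env$table$within_2sd), 2)  # the perturbed + shifted taxa
  expect_error(envelope_check(tr, X, fit, n_sims = 1), "n_sims")
})

test_that("degenerate traits and invalid matrices are rejected", {
  tr <- random_tree(5, seed = 2)
  Xc <- matrix(1, 5, 2, dimnames = list(tr$tip.label, NULL))
  expect_error(fit_model(tr, Xc, "BM"), "zero variance")
  X <- matrix(rnorm(10), 5, 2, dimnames = list(tr$tip.label, NULL))
  badR <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(model_loglik(tr, X, list(kind = "BM", R = badR, mu0 = c(0, 0))),
               "positive-definite")
  expect_error(fit_model(tr, X, "OUM"), "painting")
})
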