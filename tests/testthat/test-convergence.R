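test_that("Blomberg's K matches an independent implementation", {
  skip_if_not_installed("picante")
  set.seed(14)
  for (i in 1:4) {
    tr <- random_tree(25, seed = 50 + i)
    x <- stats::rnorm(25); names(x) <- tr$tip.label
    mine <- blomberg_k(tr, x, n_perm = 10, seed = 1)$K
    ref <- as.numeric(picante::Kcalc(x[tr$tip.label], tr))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("K is invariant to affine transformation of the trait", {
  tr <- random_tree(20, seed = 7)
  set.seed(8)
  x <- rnorm(20); names(x) <- tr$tip.label
  k1 <- blomberg_k(tr, x, n_perm = 20, seed = 2)$K
  k2 <- blomberg_k(tr, 3.7 * x + 11, n_perm = 20, seed = 2)$K
  expect_equal(k1, k2, tolerance = 1e-10)
  expect_error(blomberg_k(tr, setNames(rep(1, 20), names(x))), "constant")
})

test_that("K permutation p is small for strongly clustered traits", {
  # two deep clades with distinct means: variance among clades, K large
  tr <- read_newick(paste0("((a1:1,a2:1,a3:1,a4:1):4,",
                           "(b1:1,b2:1,b3:1,b4:1):4);"))
  x <- setNames(c(rnorm(4, -3, 0.2), rnorm(4, 3, 0.2)), tr$tip.label)
  r <- blomberg_k(tr, x, n_perm = 500, seed = 3)
  expect_gt(r$K, 1)
  expect_lt(r$p, 0.05)
})

test_that("Wilks statistic equals direct eigendecomposition and stats::manova", {
  set.seed(4)
  X <- matrix(rnorm(36), 12, 3)
  g <- factor(rep(c("u", "v", "w"), each = 4))
  ws <- mosqconv:::wilks_stat(X, g)
  expect_equal(ws$lambda, oracle_wilks(X, g), tolerance = 1e-10)
  sm <- summary(stats::manova(X ~ g), test = "Wilks")$stats
  expect_equal(ws$lambda, unname(sm[1, 2]), tolerance = 1e-10)
  expect_equal(ws$F, unname(sm[1, 3]), tolerance = 1e-8)
  expect_error(mosqconv:::wilks_stat(X, factor(rep("a", 12))), "2 groups")
  expect_error(mosqconv:::wilks_stat(X, factor(c(rep("a", 11), "b"))), ">= 2 taxa")
})

test_that("phylo MANOVA detects habitat-linked traits and respects the null", {
  ds <- simulate_dataset(n_taxa = 50, seed = 16, rate = 0.4, beta = 0.9)
  X <- run_mca(ds$morphology, 3)$traits
  groups <- ds$tip_states
  tab <- table(groups); keep <- names(tab)[tab >= 2]
  taxa <- names(groups)[groups %in% keep]
  tr <- prune_to(ds$tree, taxa)
  res <- phylo_manova(tr, X[taxa, ], groups[taxa], null = "BM",
                      n_sims = 200, seed = 5)
  expect_lt(res$p, 0.05)
  expect_true(res$lambda > 0 && res$lambda <= 1)
  # identical seed -> identical p (bit-reproducibility)
  res2 <- phylo_manova(tr, X[taxa, ], groups[taxa], null = "BM",
                       n_sims = 200, seed = 5)
  expect_identical(res$p, res2$p)
})

test_that("a fitted OUM used as its own null is plausible for OUM data", {
  ds <- simulate_dataset(n_taxa = 40, seed = 23, rate = 0.5)
  pa <- as_regime_painting(ds$history)
  regs <- pa$regimes
  theta <- matrix(rnorm(length(regs) * 2, sd = 2), length(regs), 2,
                  dimnames = list(regs, NULL))
  X <- simulate_traits(ds$tree, list(kind = "OUM", R = diag(0.3, 2),
                                     A = diag(3, 2), theta = theta),
                       painting = pa, n_sims = 1, seed = 7)[[1]]
  groups <- ds$tip_states
  tab <- table(groups); keep <- names(tab)[tab >= 2]
  taxa <- names(groups)[groups %in% keep]
  tr <- prune_to(ds$tree, taxa)
  fit <- fit_model(ds$tree, X, "OUM", painting = pa,
                   alpha_structure = "diagonal", n_restarts = 1, seed = 2)
  fit$painting <- pa
  # null simulated from the generating-model fit: observed F is typical
  res <- phylo_manova(tr, X[taxa, ], groups[taxa], null = fit,
                      n_sims = 150, seed = 9)
  expect_gt(res$p, 0.05)
})

test_that("Wheatsheaf index: exact identity, hand oracle, invariances", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  X <- matrix(c(0, 0.1, 5, 5.2), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "Dim1"))
  # focal = all taxa -> w = 1 exactly
  expect_equal(wheatsheaf(tr, X, c("A", "B", "C", "D"))$w, 1)

  # hand oracle from the explicit penalized-distance formula
  z <- (X - mean(X)) / sd(X)
  E <- as.matrix(dist(z))
  C <- ape::vcv(tr); rho <- C / max(diag(C))
  Qm <- E * (1 + rho)
  pairs_all <- Qm[upper.tri(Qm)]
  w_hand <- mean(pairs_all) / mean(Qm["C", "D"])
  res <- wheatsheaf(tr, X, c("C", "D"), n_boot = 50, seed = 1)
  expect_equal(res$w, w_hand, tolerance = 1e-12)

  # translation / positive rescaling / reordering invariance
  res_b <- wheatsheaf(tr, X * 4.2 - 7, c("C", "D"), n_boot = 50, seed = 1)
  expect_equal(res$w, res_b$w, tolerance = 1e-10)
  res_c <- wheatsheaf(tr, X[c(3, 1, 4, 2), , drop = FALSE], c("C", "D"),
                      n_boot = 50, seed = 1)
  expect_equal(res$w, res_c$w, tolerance = 1e-10)
  expect_error(wheatsheaf(tr, X, "A"), ">= 2 focal")
  expect_error(wheatsheaf(tr, X, c("A", "Z")), "absent")
})

test_that("a convergent focal group scores w above 1 with small p", {
  # two distant cherries share a derived phenotype; background is diffuse
  tr <- read_newick(paste0(
    "(((a1:1,a2:1):3,(b1:1,b2:1):3):1,((c1:1,c2:1):3,(d1:1,d2:1):3):1);"))
  set.seed(6)
  x <- setNames(rnorm(8, 0, 1.5), tr$tip.label)
  x[c("a1", "a2", "c1", "c2")] <- rnorm(4, 6, 0.1)  # convergent pair of clades
  X <- matrix(x, dimnames = list(names(x), "Dim1"))
  res <- wheatsheaf(tr, X, c("a1", "a2", "c1", "c2"), n_boot = 400, seed = 2)
  expect_gt(res$w, 1)
  expect_lt(res$p, 0.05)
})
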