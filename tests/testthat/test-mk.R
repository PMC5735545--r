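test_that("rate-matrix builders honor their constraints", {
  for (kind in c("ER", "SYM", "ARD")) {
    k <- 5
    np <- mk_n_params(kind, k)
    set.seed(1)
    Q <- build_rate_matrix(runif(np, 0.1, 2), kind, k, habitat_states())
    expect_lt(max(abs(rowSums(Q))), 1e-10)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
    if (kind == "SYM") expect_true(isSymmetric(Q))
    if (kind == "ER") expect_equal(length(unique(Q[row(Q) != col(Q)])), 1)
  }
  expect_error(build_rate_matrix(c(-1), "ER", 3), "negative")
})

test_that("no-change limit: likelihood reduces to the root prior", {
  tr <- read_newick("((A:1,B:1):1,(C:1.5,D:1.5):0.5);")
  Q <- build_rate_matrix(1e-12, "ER", 2)
  tp <- unit_tip_priors(rep(1L, 4), 2, tr$tip.label)
  expect_equal(mk_loglik(tr, tp, Q), log(1 / 2), tolerance = 1e-6)
})

test_that("pruning likelihood equals the state-enumeration oracle", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:6, 1)
    k <- sample(2:3, 1)
    tr <- random_tree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    Q <- random_Q(k, rate = runif(1, 0.3, 2))
    tp <- unit_tip_priors(sample(seq_len(k), n, replace = TRUE), k, tr$tip.label)
    # some tips ambiguous (uniform support)
    amb <- sample(n, 1)
    tp[amb, ] <- 1 / k
    ll <- mk_loglik(tr, tp, Q)
    expect_equal(ll, oracle_mk_loglik(tr, tp, Q), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to child rotation", {
  Q <- random_Q(3, seed = 2)
  tpv <- c(1L, 2L, 3L, 1L)
  t1 <- read_newick("((A:1,B:1):0.5,(C:0.7,D:0.7):0.8);")
  t2 <- read_newick("((D:0.7,C:0.7):0.8,(B:1,A:1):0.5);")
  tp <- unit_tip_priors(tpv, 3, c("A", "B", "C", "D"))
  expect_equal(mk_loglik(t1, tp, Q), mk_loglik(t2, tp, Q), tolerance = 1e-12)
})

test_that("single-state data drives the fitted rate to zero", {
  tr <- random_tree(12, seed = 8)
  tp <- unit_tip_priors(rep(2L, 12), 3, tr$tip.label)
  f <- fit_mk(tr, tp, "ER")
  expect_lte(f$rates[1], 1e-8)
  expect_equal(f$loglik, log(1 / 3), tolerance = 1e-6)
})

test_that("ER rate is recovered from simulated data", {
  # moderate rate on unit-height trees: enough events to inform the rate,
  # no saturation of the transition probabilities
  q_true <- 0.5
  Q <- build_rate_matrix(q_true, "ER", 3)
  errs <- vapply(1:12, function(i) {
    tr <- simulate_tree(200, seed = 300 + i)
    h <- simulate_discrete_history(tr, Q, 1, seed = 400 + i)
    f <- fit_mk(tr, h$tip_priors, "ER", n_restarts = 1, seed = i)
    abs(f$rates[1] - q_true) / q_true
  }, 0)
  expect_lt(median(errs), 0.25)
})

test_that("Mk fit agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  ds <- simulate_dataset(n_taxa = 60, seed = 5, rate = 0.6)
  f <- fit_mk(ds$tree, ds$tip_priors, "ER", n_restarts = 2, seed = 1)
  fm <- phytools::fitMk(ds$tree, ds$tip_states[ds$tree$tip.label],
                        model = "ER", pi = "equal")
  expect_equal(f$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-4)
  expect_equal(unname(f$rates[1]), fm$rates[1], tolerance = 1e-3)
})

test_that("AICc model ordering is invariant to taxon reordering", {
  ds <- simulate_dataset(n_taxa = 40, seed = 9, rate = 0.5)
  tab1 <- compare_mk_models(ds$tree, ds$tip_priors, kinds = c("ER", "SYM"),
                            n_restarts = 1, seed = 3)
  perm <- sample(nrow(ds$tip_priors))
  tab2 <- compare_mk_models(ds$tree, ds$tip_priors[perm, ],
                            kinds = c("ER", "SYM"), n_restarts = 1, seed = 3)
  expect_equal(tab1$kind, tab2$kind)
  expect_equal(tab1$aicc, tab2$aicc, tolerance = 1e-4)
  expect_equal(sum(tab1$weight), 1, tolerance = 1e-12)
})

test_that("marginal reconstruction matches Bayes-rule enumeration", {
  # trivial: uniform-state data
  tr <- random_tree(6, seed = 13)
  tp5 <- unit_tip_priors(rep(5L, 6), 5, tr$tip.label)
  colnames(tp5) <- habitat_states()
  # slow character: monomorphic tips pin every ancestor to the tip state
  Q5 <- build_rate_matrix(0.02, "ER", 5, habitat_states())
  asr <- marginal_asr(tr, tp5, Q5)
  expect_gt(min(asr$node_probs[, "ground_pool"]), 0.99)
  expect_equal(unname(rowSums(asr$node_probs)), rep(1, nrow(asr$node_probs)),
               tolerance = 1e-8)

  set.seed(31)
  for (rep in 1:8) {
    n <- sample(3:5, 1)
    k <- 2
    tr <- random_tree(n)
    tr$tip.label <- paste0("t", seq_len(n))
    Q <- random_Q(k, rate = runif(1, 0.5, 1.5))
    tp <- unit_tip_priors(sample(1:k, n, replace = TRUE), k, tr$tip.label)
    mine <- marginal_asr(tr, tp, Q)$node_probs
    orc <- oracle_marginal(tr, tp, Q)
    expect_equal(unname(mine), unname(orc), tolerance = 1e-8)
  }
})

test_that("multi-habitat tip priors spread mass equally", {
  tp <- make_tip_priors(c(a = "container", b = "container;rock_pool", c = NA))
  expect_equal(unname(tp["a", ]), c(1, 0, 0, 0, 0))
  expect_equal(unname(tp["b", c("container", "rock_pool")]), c(0.5, 0.5))
  expect_equal(unname(tp["c", ]), rep(0.2, 5))
  expect_error(make_tip_priors(c(a = "lagoon")), "unknown habitat")
})
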