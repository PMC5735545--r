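test_that("simulated trees are ultrametric, correctly sized, reproducible", {
  tr <- simulate_tree(2, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  expect_equal(tr$edge.length[1], tr$edge.length[2])  # a single cherry

  for (seed in 1:20) {
    n <- sample(2:60, 1)
    d <- runif(1, 0, 0.6)
    tr <- simulate_tree(n, birth = 1, death = d, seed = seed)
    expect_equal(length(tr$tip.label), n)
    expect_true(is_ultrametric(tr, rel_tol = 1e-9))
    expect_equal(tree_height(tr), 1, tolerance = 1e-9)
  }
  expect_identical(write_newick(simulate_tree(10, seed = 3)),
                   write_newick(simulate_tree(10, seed = 3)))
  expect_error(simulate_tree(10, birth = 1, death = 1), "death")
  expect_error(simulate_tree(1), "n_taxa")
})

test_that("pure-birth tree heights match n-conditioned Yule expectation", {
  # under a Yule process conditioned on n tips (rate b), the expected height
  # is E[T] = (1/b) * sum_{k=2}^{n} 1/k
  n <- 12; b <- 1
  hs <- vapply(1:400, function(i) {
    tree_height(simulate_tree(n, birth = b, seed = 1000 + i,
                              scale_height = FALSE))
  }, 0)
  expected <- sum(1 / (2:n)) / b
  se <- sd(hs) / sqrt(length(hs))
  expect_lt(abs(mean(hs) - expected), 4 * se)
})

test_that("forward habitat histories are structurally consistent", {
  tr <- simulate_tree(20, seed = 5)
  Q <- build_rate_matrix(0.3, "ER", 5, habitat_states())
  h <- simulate_discrete_history(tr, Q, "ground_pool", seed = 2)
  segsum <- vapply(h$map$edge_maps, sum, 0)
  expect_lt(max(abs(segsum - tr$edge.length)), 1e-9)
  expect_equal(unname(h$tip_states),
               h$map$states[h$map$node_states[seq_len(20)]])
  expect_equal(rowSums(h$tip_priors), setNames(rep(1, 20), tr$tip.label))

  # zero generator: no change anywhere
  Q0 <- matrix(0, 3, 3)
  h0 <- simulate_discrete_history(tr, Q0, 2, seed = 3)
  expect_true(all(h0$map$node_states == 2))
  expect_equal(nrow(h0$map$events), 0)
})

test_that("per-branch transition counts match the unconditional mean", {
  # a two-state chain starting in state 1 on one branch of length t:
  # E[N(t)] = sum_s q_s int_0^t P_{1s}(u) du, by quadrature
  q12 <- 0.9; q21 <- 0.4; t_len <- 1.7
  Q <- matrix(c(-q12, q12, q21, -q21), 2, 2, byrow = TRUE)
  tr <- ape::stree(2, "star"); tr$edge.length <- c(t_len, t_len)
  set.seed(11)
  counts <- replicate(4000, {
    h <- simulate_discrete_history(tr, Q, 1)
    sum(h$map$events$edge == 1)
  })
  p11 <- function(u) q21 / (q12 + q21) + q12 / (q12 + q21) * exp(-(q12 + q21) * u)
  expected <- stats::integrate(function(u) q12 * p11(u) + q21 * (1 - p11(u)),
                               0, t_len)$value
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("tip-state frequencies approach the stationary distribution", {
  # star tree: tips are independent realizations of a long chain
  n <- 400
  tr <- ape::stree(n, "star"); tr$edge.length <- rep(8, n)
  Q <- build_rate_matrix(0.5, "ER", 5, habitat_states())
  h <- simulate_discrete_history(tr, Q, "container", seed = 9)
  freqs <- table(factor(h$tip_states, levels = habitat_states())) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(freqs - 0.2) < 4 * se))
})

test_that("morphology generator respects shape, levels and effect direction", {
  ds <- simulate_dataset(n_taxa = 30, seed = 4, n_chars = 25)
  expect_equal(dim(ds$morphology), c(30L, 25L))
  expect_true(all(grepl("^l[0-9]+$", ds$morphology)))
  expect_error(simulate_categorical_morphology(ds$tip_states, 5, levels = 1),
               "levels")
  expect_error(simulate_categorical_morphology(ds$tip_states, 5, beta = 1.2),
               "beta")

  # beta = 1 with many characters separates habitats in MCA space far more
  # than beta = 0
  sep <- function(beta) {
    m <- simulate_categorical_morphology(ds$tip_states, 60, 2:4, beta,
                                         seed = 31)
    sc <- suppressWarnings(run_mca(m, 2))$traits[, 1]
    gp <- ds$tip_states == "ground_pool"
    if (sum(gp) < 2 || sum(!gp) < 2) return(NA_real_)
    abs(mean(sc[gp]) - mean(sc[!gp])) /
      sqrt((stats::var(sc[gp]) + stats::var(sc[!gp])) / 2)
  }
  expect_gt(sep(1), sep(0))
})

test_that("identical config and seed give byte-identical datasets", {
  a <- simulate_dataset(n_taxa = 18, seed = 77)
  b <- simulate_dataset(n_taxa = 18, seed = 77)
  expect_identical(a, b)
  c <- simulate_dataset(n_taxa = 18, seed = 78)
  expect_false(identical(a$morphology, c$morphology))
})

test_that("habitat frequencies mirror the study-clade specialist counts", {
  f <- habitat_frequencies()
  expect_equal(sum(f), 1)
  expect_equal(names(which.max(f)), "ground_pool")
  expect_gt(f[["container"]], 0.4)
  expect_equal(unname(f[["crab_hole"]]), 4 / 282, tolerance = 1e-12)
})
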