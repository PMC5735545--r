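write_tmp <- function(lines) {
  f <- tempfile(fileext = ".phy")
  writeLines(lines, f)
  f
}

test_that("PHYLIP reader handles strict, relaxed and interleaved dialects", {
  relaxed <- write_tmp(c("3 8",
                         "Aedes_aegypti ACGTACGT",
                         "Aedes_albopictus ACGT--GT",
                         "Culex_pipiens NNNNACGT"))
  m <- read_alignment(relaxed)
  expect_equal(dim(m), c(3L, 8L))
  expect_equal(rownames(m)[1], "Aedes_aegypti")
  expect_equal(paste(m[2, ], collapse = ""), "ACGT--GT")

  strict <- write_tmp(c("2 8",
                        paste0("taxonA    ", "ACGTACGT"),
                        paste0("taxonB    ", "ACGTTCGT")))
  ms <- read_alignment(strict)
  # cross-check strict dialect against the ape reader
  mape <- toupper(unclass(ape::read.dna(strict, format = "sequential",
                                        as.character = TRUE, as.matrix = TRUE)))
  expect_equal(unname(ms), unname(mape))

  inter <- write_tmp(c("2 12", "A ACGT", "B TTTT", "ACGT", "CCCC", "ACGT", "GGGG"))
  mi <- read_alignment(inter)
  expect_equal(paste(mi[1, ], collapse = ""), "ACGTACGTACGT")
  expect_equal(paste(mi[2, ], collapse = ""), "TTTTCCCCGGGG")

  expect_error(read_alignment(write_tmp(c("2 9", "A ACGT", "B ACGT"))),
               "lengths")
  expect_error(read_alignment(write_tmp(c("x y", "A ACGT"))), "header")
})

test_that("partition files parse intervals and codon strides", {
  f <- tempfile()
  writeLines(c("DNA, COI = 1-6",
               "DNA, COI_pos3 = 7-12\\3",
               "DNA, multi = 13-14, 17-18"), f)
  p <- read_partitions(f)
  expect_named(p, c("COI", "COI_pos3", "multi"))
  expect_equal(p$COI, 1:6)
  expect_equal(p$COI_pos3, c(7, 10))
  expect_equal(p$multi, c(13, 14, 17, 18))
  f2 <- tempfile(); writeLines("no equals here", f2)
  expect_error(read_partitions(f2), "parse")
})

test_that("coverage treats gaps/?/N as absent and counts markers", {
  aln <- rbind(A = strsplit("ACGTAC--", "")[[1]],
               B = rep("-", 8))
  parts <- list(m1 = 1:4, m2 = 5:8)
  cov <- coverage_stats(aln, parts)
  expect_equal(cov$per_taxon$non_gap, c(6L, 0L))
  expect_equal(cov$per_taxon$n_markers, c(2L, 0L))
  expect_equal(cov$totals$n_columns, 8)
  expect_equal(unname(cov$totals$taxa_with_ge_k_markers), c(1L, 1L))

  # '?' and 'N' also absent; marker present iff >= 1 non-absent site
  aln2 <- rbind(A = c("?", "N", "-", "A"), B = c("A", "C", "G", "T"))
  cov2 <- coverage_stats(aln2, list(m1 = 1:3, m2 = 4))
  expect_equal(cov2$per_taxon$non_gap, c(1L, 4L))
  expect_equal(cov2$per_taxon$n_markers, c(1L, 2L))

  expect_error(coverage_stats(aln, list(bad = 7:9)), "out of bounds")
})

test_that("coverage totals are invariant to row reordering", {
  set.seed(7)
  aln <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 60, replace = TRUE),
                6, 10, dimnames = list(paste0("t", 1:6), NULL))
  parts <- list(m1 = 1:5, m2 = 6:10)
  a <- coverage_stats(aln, parts)$totals
  b <- coverage_stats(aln[sample(6), ], parts)$totals
  expect_equal(a, b)
})

test_that("kendall tau-b matches enumeration oracle and handles ties", {
  expect_equal(kendall_tau(c(1, 2, 3), c(10, 20, 30))$tau, 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(3, 2, 1))$tau, -1)
  set.seed(11)
  for (i in 1:20) {
    n <- sample(c(8, 15, 30, 50), 1)
    x <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- x + sample(-2:2, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    kt <- kendall_tau(x, y)
    expect_equal(kt$tau, oracle_kendall_tau(x, y), tolerance = 1e-12)
    ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
    expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-10)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("coverage/branch-length QC runs end to end on matched data", {
  tr <- random_tree(8, seed = 3)
  set.seed(4)
  aln <- matrix(sample(c("A", "C", "-", "-"), 8 * 50, replace = TRUE), 8, 50,
                dimnames = list(tr$tip.label, NULL))
  res <- coverage_branchlength_tau(tr, aln)
  expect_true(abs(res$tau) <= 1)
  expect_equal(res$n, 8)
  expect_true(res$p > 0 && res$p <= 1)
})
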