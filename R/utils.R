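#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim optimize rnorm runif rpois rexp rbinom sd var cov
#'   pnorm pf qnorm setNames aggregate cophenetic quantile
#' @importFrom utils head tail
NULL

# Small-sample corrected Akaike information criterion.
# n_obs convention for multivariate trait models: n_taxa * n_traits.
aicc <- function(loglik, k, n_obs) {
  if (n_obs <= k + 1) stop("AICc undefined: n_obs <= K + 1 (n_obs=", n_obs, ", K=", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n_obs - k - 1)
}

# Add-one-corrected empirical p-value: proportion of null values >= observed.
p_add_one <- function(null_values, observed) {
  (1 + sum(null_values >= observed)) / (1 + length(null_values))
}

#' Derive reproducible child seeds from a single master seed
#'
#' A single pipeline seed fans out deterministically to one child seed per
#' named stage, so toggling one stochastic stage does not perturb the draws of
#' another.
#'
#' @param seed Integer master seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector of child seeds (all below 2^31).
#' @export
derive_seeds <- function(seed, stages) {
  stopifnot(is.character(stages), length(stages) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  stats::setNames(s, stages)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Normalize taxon labels for matching between trees and tables: trim
# whitespace, collapse runs of spaces, and unify spaces with underscores.
normalize_labels <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", x)
  x <- gsub("\\s+", " ", x)
  gsub(" ", "_", x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
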