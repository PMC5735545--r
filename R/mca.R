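#' Multiple correspondence analysis of a categorical character matrix
#'
#' Indicator-matrix MCA: the taxa x characters nominal matrix is expanded to
#' a 0/1 indicator, scaled to correspondence proportions, centered by the
#' rank-one margin product, whitened by row/column masses, and decomposed by
#' SVD. Principal inertias are squared singular values; their sum equals
#' J/Q - 1 (J total categories, Q characters). Row principal coordinates for
#' the first `n_keep` dimensions form the continuous trait matrix used by all
#' downstream analyses.
#'
#' @param m Data frame or character matrix of taxa (rows) x characters
#'   (columns); cells are category codes; `NA` marks missing.
#' @param n_keep Number of dimensions to retain as traits.
#' @param missing Either "own-level" (missing becomes an extra category per
#'   character, keeping all taxa; default) or "complete-case" (rows with any
#'   missing cell are dropped).
#' @return Object of class `mca_result`: `eigenvalues`, `percent` (summing to
#'   100), `row_coords` (all dimensions), `col_coords`, `traits` (taxa x
#'   `n_keep` matrix, columns `Dim1`...), `J`, `Q`, `dropped_characters`.
#' @export
run_mca <- function(m, n_keep = 5, missing = c("own-level", "complete-case")) {
  missing <- match.arg(missing)
  if (is.matrix(m)) m <- as.data.frame(m, stringsAsFactors = FALSE)
  if (!nrow(m) || !ncol(m)) stop("validation error: empty matrix")
  taxa <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (missing == "complete-case") {
    ok <- stats::complete.cases(m)
    m <- m[ok, , drop = FALSE]; taxa <- taxa[ok]
    if (nrow(m) < 3) stop("validation error: fewer than 3 complete cases")
  } else {
    m[] <- lapply(m, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ".missing"
      col
    })
  }
  all_missing <- vapply(m, function(col) all(is.na(col) | col == ".missing"), TRUE)
  if (any(all_missing)) stop("validation error: all-missing character(s): ",
                             paste(names(m)[all_missing], collapse = ", "))
  nlev <- vapply(m, function(col) length(unique(col[!is.na(col)])), 0L)
  dropped <- names(m)[nlev < 2]
  if (length(dropped)) {
    warning("dropping single-level character(s): ", paste(dropped, collapse = ", "))
    m <- m[, nlev >= 2, drop = FALSE]
  }
  if (!ncol(m)) stop("validation error: no characters with >= 2 levels")
  Qn <- ncol(m)
  Z <- do.call(cbind, lapply(names(m), function(ch) {
    f <- factor(m[[ch]])
    ind <- stats::model.matrix(~ f - 1)
    colnames(ind) <- paste0(ch, ":", levels(f))
    ind
  }))
  J <- ncol(Z)
  P <- Z / sum(Z)
  r <- rowSums(P); cmass <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cmass) %*% diag(1 / sqrt(cmass))
  sv <- svd(S)
  keep_sv <- sv$d > 1e-10
  d <- sv$d[keep_sv]
  lambda <- d^2
  Fco <- diag(1 / sqrt(r)) %*% sv$u[, keep_sv, drop = FALSE] %*% diag(d, length(d))
  Gco <- diag(1 / sqrt(cmass)) %*% sv$v[, keep_sv, drop = FALSE] %*% diag(d, length(d))
  dn <- paste0("Dim", seq_along(lambda))
  dimnames(Fco) <- list(taxa, dn); dimnames(Gco) <- list(colnames(Z), dn)
  if (n_keep > length(lambda))
    stop("n_keep exceeds number of dimensions (", length(lambda), ")")
  structure(list(
    eigenvalues = lambda,
    percent = 100 * lambda / sum(lambda),
    row_coords = Fco, col_coords = Gco,
    traits = Fco[, seq_len(n_keep), drop = FALSE],
    J = J, Q = Qn, row_mass = r, dropped_characters = dropped
  ), class = "mca_result")
}

#' Fix the arbitrary sign of MCA dimensions by anchoring
#'
#' SVD axis signs are arbitrary; narrative interpretation (e.g. "container
#' taxa score positive on dimension 1") requires fixing them. Each dimension
#' is flipped so the anchor — a taxon's coordinate, or the mean coordinate of
#' a set of taxa — has the requested sign. Eigenvalues are untouched.
#'
#' @param res `mca_result`.
#' @param anchor Taxon label or character vector of labels (group mean).
#' @param sign Desired sign (+1 or -1) of the anchor coordinate.
#' @return The reoriented `mca_result`.
#' @export
orient_dimensions <- function(res, anchor, sign = 1) {
  stopifnot(inherits(res, "mca_result"), sign %in% c(-1, 1))
  idx <- match(normalize_labels(anchor), normalize_labels(rownames(res$row_coords)))
  if (anyNA(idx)) stop("anchor taxa not found: ",
                       paste(anchor[is.na(idx)], collapse = ", "))
  a <- colMeans(res$row_coords[idx, , drop = FALSE])
  if (any(a == 0)) stop("anchor coordinate exactly 0 on dimension(s): ",
                        paste(which(a == 0), collapse = ", "))
  flip <- ifelse(base::sign(a) == sign, 1, -1)
  res$row_coords <- sweep(res$row_coords, 2, flip, "*")
  res$col_coords <- sweep(res$col_coords, 2, flip, "*")
  res$traits <- res$row_coords[, seq_len(ncol(res$traits)), drop = FALSE]
  res
}
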