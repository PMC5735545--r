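#' Read a nucleotide alignment (PHYLIP or FASTA)
#'
#' PHYLIP is parsed by a dialect-detecting reader: a header line `n m` is
#' required; the sequential body is accepted in either the strict dialect
#' (10-character fixed-width names) or the relaxed dialect (whitespace after
#' an arbitrary-length name), auto-detected per file. Interleaved continuation
#' blocks are supported. FASTA files (leading `>`) go through
#' [ape::read.dna()].
#'
#' @param path Path to the alignment file.
#' @return Character matrix (taxa x columns, upper-case), rownames = taxon
#'   labels.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("^>", first)) {
    dna <- ape::read.dna(path, format = "fasta", as.character = TRUE, as.matrix = TRUE)
    m <- toupper(unclass(dna))
    rownames(m) <- normalize_labels(rownames(m))
    return(validate_alignment(m))
  }
  read_phylip(path)
}

# Hand-rolled PHYLIP reader: dialect (strict 10-char vs relaxed
# whitespace-delimited names) is auto-detected; sequential and interleaved
# layouts both accepted.
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  hdr <- strsplit(gsub("^\\s+", "", lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop("PHYLIP parse error: header must be 'ntaxa ncols'")
  n <- as.integer(hdr[1]); ncols <- as.integer(hdr[2])
  body <- lines[-1]
  if (length(body) < n) stop("PHYLIP parse error: fewer lines than taxa")

  parse_named_line <- function(ln) {
    # relaxed: name<ws>seq ; strict: 10-char name then seq
    if (grepl("^\\S+\\s+\\S", ln)) {
      sp <- regexpr("\\s+", ln)
      name <- substr(ln, 1, sp - 1)
      seq <- gsub("\\s", "", substr(ln, sp, nchar(ln)))
    } else {
      name <- gsub("\\s+$", "", substr(ln, 1, 10))
      seq <- gsub("\\s", "", substr(ln, 11, nchar(ln)))
    }
    list(name = name, seq = seq)
  }

  first_block <- lapply(body[seq_len(n)], parse_named_line)
  names_v <- vapply(first_block, `[[`, "", "name")
  seqs <- vapply(first_block, `[[`, "", "seq")
  # interleaved continuation blocks: bare sequence lines in taxon order
  rest <- body[-seq_len(n)]
  i <- 0L
  for (ln in rest) {
    i <- i %% n + 1L
    seqs[i] <- paste0(seqs[i], gsub("\\s", "", ln))
  }
  if (any(nchar(seqs) != ncols))
    stop("PHYLIP parse error: sequence lengths ", paste(unique(nchar(seqs)), collapse = "/"),
         " do not match header ", ncols)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- normalize_labels(names_v)
  validate_alignment(m)
}

validate_alignment <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1) stop("validation error: empty alignment")
  if (any(duplicated(rownames(m)))) stop("validation error: duplicate taxon names")
  m
}

#' Read a RAxML-style partition file
#'
#' Accepts lines of the form `DNA, name = 1-100, 200-300\3`; codon strides
#' (`\3`) and multiple comma-separated intervals per marker are supported.
#'
#' @param path Path to the partition file.
#' @return Named list; each element an integer vector of 1-based alignment
#'   columns belonging to that marker.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines)]
  out <- list()
  for (ln in lines) {
    lhs <- sub("=.*", "", ln)
    name <- gsub("^\\s+|\\s+$", "", sub("^[^,]*,", "", lhs))
    rhs <- sub(".*=", "", ln)
    cols <- integer(0)
    for (piece in strsplit(rhs, ",")[[1]]) {
      piece <- gsub("\\s", "", piece)
      stride <- 1L
      if (grepl("\\\\", piece)) {
        stride <- as.integer(sub(".*\\\\", "", piece))
        piece <- sub("\\\\.*", "", piece)
      }
      ab <- as.integer(strsplit(piece, "-")[[1]])
      if (length(ab) == 1) ab <- c(ab, ab)
      if (anyNA(ab) || ab[2] < ab[1]) stop("partition parse error in: ", ln)
      cols <- c(cols, seq(ab[1], ab[2], by = stride))
    }
    out[[name]] <- sort(unique(cols))
  }
  if (!length(out)) stop("partition parse error: no 'name = interval' lines found")
  out
}

# Characters treated as "absent" when counting coverage (case-insensitive;
# matrix is upper-cased on read).
ABSENT_CHARS <- c("-", "?", "N")

#' Per-taxon alignment coverage and marker presence
#'
#' Counts non-gap nucleotides per taxon (`-`, `?`, `N` treated as absent) and,
#' given a partition map, which markers each taxon has at least one
#' non-absent site in.
#'
#' @param aln Character matrix from [read_alignment()].
#' @param partitions Optional named list from [read_partitions()].
#' @return List with `per_taxon` (data.frame: taxon, non_gap, proportion,
#'   n_markers), `marker_presence` (logical matrix), `totals` (n_taxa,
#'   n_columns, mean_coverage, and counts of taxa with >= k markers).
#' @export
coverage_stats <- function(aln, partitions = NULL) {
  validate_alignment(aln)
  absent <- matrix(aln %in% ABSENT_CHARS, nrow = nrow(aln))
  non_gap <- rowSums(!absent)
  per_taxon <- data.frame(
    taxon = rownames(aln),
    non_gap = as.integer(non_gap),
    proportion = non_gap / ncol(aln),
    stringsAsFactors = FALSE
  )
  marker_presence <- NULL
  if (!is.null(partitions)) {
    bad <- vapply(partitions, function(cols) any(cols < 1 | cols > ncol(aln)), TRUE)
    if (any(bad))
      stop("validation error: partition interval out of bounds for markers: ",
           paste(names(partitions)[bad], collapse = ", "))
    marker_presence <- vapply(partitions, function(cols) {
      rowSums(!absent[, cols, drop = FALSE]) > 0
    }, logical(nrow(aln)))
    rownames(marker_presence) <- rownames(aln)
    per_taxon$n_markers <- as.integer(rowSums(marker_presence))
  }
  totals <- list(
    n_taxa = nrow(aln), n_columns = ncol(aln),
    mean_coverage = mean(non_gap)
  )
  if (!is.null(marker_presence)) {
    kmax <- length(partitions)
    totals$taxa_with_ge_k_markers <-
      stats::setNames(vapply(seq_len(kmax), function(k) sum(per_taxon$n_markers >= k), 0L),
                      paste0("ge_", seq_len(kmax)))
  }
  structure(list(per_taxon = per_taxon, marker_presence = marker_presence, totals = totals),
            class = "coverage_report")
}

#' Kendall's tau-b with tie-corrected normal approximation
#'
#' Used as the branch-length/coverage QC: a strong correlation between
#' terminal branch length and how much sequence a taxon contributes would
#' indicate branch-length bias from missing data.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `tau` (tau-b), `z` (tie-corrected normal score of the
#'   concordance statistic S), and two-sided `p`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined statistic: constant vector")
  # S and pair counts, O(n^2) on at most a few hundred taxa
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  S <- sum((dx * dy)[up])
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  # tie-corrected variance of S (Kendall 1970)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v0 <- n * (n - 1) * (2 * n + 5)
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- S / sqrt(varS)
  list(tau = tau, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Branch-length / coverage QC correlation
#'
#' Kendall's tau between each taxon's terminal branch length and its
#' alignment coverage (proportion of non-gap sites by default, raw counts
#' optionally).
#'
#' @param tree `phylo` whose tips appear in the alignment.
#' @param aln Character alignment matrix.
#' @param use Either "proportion" (default) or "count".
#' @return As [kendall_tau()], plus `n` taxa used.
#' @export
coverage_branchlength_tau <- function(tree, aln, use = c("proportion", "count")) {
  use <- match.arg(use)
  cov <- coverage_stats(aln)$per_taxon
  tl <- terminal_branch_lengths(tree)
  common <- intersect(names(tl), cov$taxon)
  if (length(common) < 3) stop("fewer than 3 taxa shared between tree and alignment")
  v <- if (use == "proportion") cov$proportion else cov$non_gap
  names(v) <- cov$taxon
  res <- kendall_tau(v[common], tl[common])
  res$n <- length(common)
  res
}
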