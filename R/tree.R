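#' Read a rooted phylogeny from a newick string or file
#'
#' Thin validating wrapper over [ape::read.tree()]. The returned object is an
#' ordinary `phylo`, the container used throughout the package. Tip labels are
#' normalized (whitespace trimmed, internal spaces unified to underscores) so
#' that trees and data tables written by different tools can be matched by
#' exact string equality.
#'
#' @param x Newick string (containing "(") or path to a newick file.
#' @return A `phylo` object with unique tip labels and non-negative branch
#'   lengths.
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  tr <- if (grepl("\\(", x)) {
    txt <- x
    semi <- regexpr(";", txt)
    if (semi < 0) stop("newick parse error: no terminating ';' (offset ", nchar(txt), ")")
    .check_newick_syntax(txt)
    ape::read.tree(text = txt)
  } else {
    if (!file.exists(x)) stop("tree file not found: ", x)
    .check_newick_syntax(paste(readLines(x, warn = FALSE), collapse = ""))
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("newick parse error: unreadable tree")
  tr$tip.label <- normalize_labels(tr$tip.label)
  validate_phylogeny(tr)
  tr
}

# Cheap structural scan so malformed strings report a character offset
# instead of ape's silent NULL.
.check_newick_syntax <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("newick parse error: unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L) stop("newick parse error: ", depth, " unclosed '(' at offset ", length(chars))
  invisible(TRUE)
}

#' Validate the structural invariants of a phylogeny
#'
#' Checks: exactly one root, unique non-empty tip labels, branch lengths
#' present and non-negative. Polytomies are allowed.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (any(tree$tip.label == "")) stop("validation error: empty tip label")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("validation error: duplicate tip labels: ", paste(unique(dup), collapse = ", "))
  if (is.null(tree$edge.length)) stop("validation error: branch lengths missing")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("validation error: negative or missing branch lengths")
  # exactly one root: one node with no incoming edge
  nodes <- unique(as.vector(tree$edge))
  roots <- setdiff(tree$edge[, 1], tree$edge[, 2])
  if (length(roots) != 1) stop("validation error: tree must have exactly one root")
  invisible(tree)
}

#' Write a phylogeny to a newick string
#'
#' @param tree A `phylo` object.
#' @param digits Number of significant digits for branch lengths.
#' @return Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

# Depth (distance from root) of every node, root = 0. Indexed by node id.
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  depth <- numeric(n + m)
  root <- n + 1L
  # preorder traversal
  eo <- ape::reorder.phylo(tree, "postorder")
  edges <- eo$edge[rev(seq_len(nrow(eo$edge))), , drop = FALSE]
  lens <- eo$edge.length[rev(seq_len(nrow(eo$edge)))]
  for (i in seq_len(nrow(edges))) {
    depth[edges[i, 2]] <- depth[edges[i, 1]] + lens[i]
  }
  depth
}

#' Tree height and ultrametricity test
#'
#' A tree is declared ultrametric when all root-to-tip path lengths agree
#' within `rel_tol` times the tree height. The default tolerance admits the
#' numerically-near-ultrametric output of penalized-likelihood time
#' calibration.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param rel_tol Relative tolerance on root-to-tip path spread.
#' @return `is_ultrametric`: logical. `tree_height`: maximum root-to-tip
#'   distance.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylogeny(tree)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  h <- max(d)
  if (h <= 0) stop("degenerate input: zero-height tree")
  (max(d) - min(d)) <= rel_tol * h
}

#' @rdname is_ultrametric
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Prune a tree to a set of tips
#'
#' Keeps exactly the requested tips, suppressing unbranched internal nodes and
#' summing their branch lengths, so all pairwise path lengths between kept
#' tips are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to keep (>= 2).
#' @return Pruned `phylo`.
#' @export
prune_to <- function(tree, keep) {
  keep <- normalize_labels(keep)
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2) stop("need at least 2 tips to keep")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

# Terminal branch length per tip, named by tip label.
terminal_branch_lengths <- function(tree) {
  n <- length(tree$tip.label)
  idx <- match(seq_len(n), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}
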