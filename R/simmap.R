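#' Sample stochastic character maps under a fixed Mk generator
#'
#' Each map is drawn in two stages: node states are sampled from their
#' conditional distributions given the tip data and Q (root from the
#' prior-weighted root partials, then each child given its parent), and each
#' branch history is sampled exactly, conditional on its endpoint states, by
#' endpoint-conditioned uniformization (dominating rate = max |Q_ii|; the
#' number of dominated-chain jumps is drawn from its exact conditional
#' distribution, jump times are order statistics of uniforms, and the jump
#' chain is sampled by forward-backward filtering). No rejection loop is
#' needed; the sampler is exact and reproducible under a seed.
#'
#' @inheritParams mk_loglik
#' @param n_maps Number of maps to draw.
#' @param seed Optional integer seed.
#' @return List of `stochastic_map` objects. Each has `node_states` (state
#'   index per node, tips included), `edge_maps` (per edge of `tree$edge`, a
#'   named numeric vector of segment durations in order along the branch,
#'   names = state), and `events` (data.frame edge, time, from, to).
#' @export
sample_stochastic_maps <- function(tree, tip_priors, Q, n_maps = 1000,
                                   root_prior = NULL, seed = NULL) {
  validate_rate_matrix(Q)
  stopifnot(n_maps >= 1)
  tp <- .align_tips(tree, tip_priors)
  k <- nrow(Q)
  states <- colnames(tp) %||% as.character(seq_len(k))
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  if (!is.null(seed)) set.seed(seed)

  pr <- .mk_prune(tree, tp, Q)
  n <- length(tree$tip.label)
  root <- n + 1L
  po <- pr$po; Parr <- pr$Parr; L <- pr$L
  pre_edges <- rev(seq_len(nrow(po$edge)))  # preorder sweep of postorder edges

  # map postorder edge index -> index of same edge in tree$edge
  edge_key <- function(E) paste(E[, 1], E[, 2])
  po2tree <- match(edge_key(po$edge), edge_key(tree$edge))

  omega <- max(-diag(Q))
  unif <- .uniformization_cache(Q, omega)

  root_post <- root_prior * L[root, ]
  root_post <- root_post / sum(root_post)

  lapply(seq_len(n_maps), function(rep) {
    node_state <- integer(n + tree$Nnode)
    node_state[root] <- sample.int(k, 1, prob = root_post)
    ne <- nrow(po$edge)
    edge_maps <- vector("list", ne)
    events <- vector("list", ne)
    for (e in pre_edges) {
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      w <- Parr[node_state[par], , e] * L[ch, ]
      node_state[ch] <- sample.int(k, 1, prob = w)
      bp <- .sample_branch_path(node_state[par], node_state[ch],
                                po$edge.length[e], Q, omega, unif,
                                Parr[, , e])
      edge_maps[[po2tree[e]]] <- stats::setNames(bp$durations, states[bp$states])
      if (nrow(bp$events)) {
        ev <- bp$events
        ev$edge <- po2tree[e]
        events[[po2tree[e]]] <- ev
      }
    }
    ev <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
    if (is.null(ev)) ev <- data.frame(time = numeric(0), from = integer(0),
                                      to = integer(0), edge = integer(0))
    structure(list(node_states = node_state, edge_maps = edge_maps,
                   events = ev, states = states, tree_ntip = n,
                   edge = tree$edge, edge.length = tree$edge.length),
              class = "stochastic_map")
  })
}

# Shared cache of powers of the uniformized kernel R = I + Q/omega.
.uniformization_cache <- function(Q, omega) {
  k <- nrow(Q)
  env <- new.env(parent = emptyenv())
  env$R <- if (omega > 0) diag(k) + Q / omega else diag(k)
  env$powers <- list(diag(k))  # powers[[m+1]] = R^m
  env$get <- function(m) {
    while (length(env$powers) < m + 1) {
      env$powers[[length(env$powers) + 1]] <-
        env$powers[[length(env$powers)]] %*% env$R
    }
    env$powers[[m + 1]]
  }
  env
}

# Exact endpoint-conditioned path on one branch.
.sample_branch_path <- function(a, b, t, Q, omega, unif, Pab_mat) {
  k <- nrow(Q)
  if (omega <= 0 || t <= 0) {
    if (a != b) stop("branch sampling failure: zero-rate branch with differing endpoints")
    return(list(states = a, durations = t,
                events = data.frame(time = numeric(0), from = integer(0), to = integer(0))))
  }
  pab <- Pab_mat[a, b]
  if (pab <= 0) stop("branch sampling failure: impossible endpoint pair")
  # draw number of dominated-chain jumps N | a, b, t
  u <- stats::runif(1)
  cum <- 0; m <- -1L
  lam <- omega * t
  repeat {
    m <- m + 1L
    pm <- stats::dpois(m, lam) * unif$get(m)[a, b] / pab
    cum <- cum + pm
    if (u <= cum || m > 10000L) break
  }
  if (m > 10000L) stop("branch sampling failure: uniformization series did not terminate")
  N <- m
  if (N == 0) {
    return(list(states = a, durations = t,
                events = data.frame(time = numeric(0), from = integer(0), to = integer(0))))
  }
  times <- sort(stats::runif(N)) * t
  R <- unif$R
  chain <- integer(N + 1); chain[1] <- a
  for (j in seq_len(N)) {
    back <- unif$get(N - j)[, b]
    w <- R[chain[j], ] * back
    chain[j + 1] <- sample.int(k, 1, prob = w)
  }
  # collapse virtual (self) jumps into segments
  keep <- which(chain[-1] != chain[-(N + 1)])
  if (!length(keep)) {
    return(list(states = a, durations = t,
                events = data.frame(time = numeric(0), from = integer(0), to = integer(0))))
  }
  ev_times <- times[keep]
  seg_states <- c(a, chain[keep + 1])
  seg_dur <- diff(c(0, ev_times, t))
  list(states = seg_states, durations = seg_dur,
       events = data.frame(time = ev_times, from = seg_states[-length(seg_states)],
                           to = seg_states[-1]))
}

#' Summarize stochastic maps into node posteriors and transition counts
#'
#' @param maps List of `stochastic_map` objects from the same tree.
#' @return List with `node_probs` (nodes x states frequency matrix, rows sum
#'   to 1; rownames are ape node ids, tips included), `mean_transitions`
#'   (states x states mean count matrix), `n_maps`.
#' @export
summarize_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  e1 <- maps[[1]]$edge
  same <- vapply(maps, function(m) identical(m$edge, e1) &&
                   identical(m$states, maps[[1]]$states), TRUE)
  if (!all(same)) stop("maps come from different trees")
  states <- maps[[1]]$states
  k <- length(states)
  nn <- length(maps[[1]]$node_states)
  counts <- matrix(0, nn, k, dimnames = list(as.character(seq_len(nn)), states))
  trans <- matrix(0, k, k, dimnames = list(states, states))
  for (m in maps) {
    counts[cbind(seq_len(nn), m$node_states)] <-
      counts[cbind(seq_len(nn), m$node_states)] + 1
    if (nrow(m$events)) {
      tt <- table(factor(m$events$from, levels = seq_len(k)),
                  factor(m$events$to, levels = seq_len(k)))
      trans <- trans + tt
    }
  }
  list(node_probs = counts / length(maps), mean_transitions = trans / length(maps),
       n_maps = length(maps))
}

#' Convert one stochastic map into a regime painting
#'
#' A regime painting assigns every point on every branch to a habitat regime;
#' it is the input multi-optimum OU models condition on.
#'
#' @param map A `stochastic_map`.
#' @param tree The `phylo` the map was sampled on (for pruning support).
#' @return Object of class `regime_painting`: list with `edge_maps` (per
#'   tree-edge named duration vectors), `regimes` (states present),
#'   `node_states`, `edge`, `states`.
#' @export
as_regime_painting <- function(map, tree = NULL) {
  structure(list(edge_maps = map$edge_maps, node_states = map$node_states,
                 states = map$states,
                 regimes = sort(unique(unlist(lapply(map$edge_maps, names)))),
                 edge = map$edge, edge.length = map$edge.length,
                 tree_ntip = map$tree_ntip),
            class = "regime_painting")
}

#' Restrict a stochastic map / regime painting to a pruned tree
#'
#' When the comparative analysis runs on a subset of taxa (e.g. only those
#' with morphological scores), habitat maps sampled on the full tree must be
#' carried over. Each edge of the pruned tree corresponds to a root-ward path
#' in the full tree; the segment lists along that path are concatenated.
#'
#' @param map `stochastic_map` sampled on `full_tree`.
#' @param full_tree The tree the map was sampled on.
#' @param pruned_tree A tree whose tips are a subset of `full_tree`'s.
#' @return A `regime_painting` on `pruned_tree`.
#' @export
prune_map_to <- function(map, full_tree, pruned_tree) {
  n_full <- length(full_tree$tip.label)
  n_sub <- length(pruned_tree$tip.label)
  depth_full <- node_depths(full_tree)
  # node heights above root in full tree for every pruned-tree node:
  # identify each pruned node by the MRCA of its descendant tips in full tree
  sub_node_full <- integer(n_sub + pruned_tree$Nnode)
  for (tip in seq_len(n_sub)) {
    sub_node_full[tip] <- match(pruned_tree$tip.label[tip], full_tree$tip.label)
  }
  if (anyNA(sub_node_full[seq_len(n_sub)]))
    stop("pruned tree tips not all present in full tree")
  for (nd in (n_sub + 1):(n_sub + pruned_tree$Nnode)) {
    tips_below <- ape::extract.clade(pruned_tree, nd)$tip.label
    sub_node_full[nd] <- if (length(tips_below) == length(full_tree$tip.label))
      n_full + 1L else ape::getMRCA(full_tree, match(tips_below, full_tree$tip.label))
  }
  # full-tree parent lookup
  parent_full <- integer(n_full + full_tree$Nnode)
  parent_full[full_tree$edge[, 2]] <- full_tree$edge[, 1]
  edge_of_child <- match(seq_len(n_full + full_tree$Nnode), full_tree$edge[, 2])

  edge_maps <- vector("list", nrow(pruned_tree$edge))
  for (e in seq_len(nrow(pruned_tree$edge))) {
    top <- sub_node_full[pruned_tree$edge[e, 1]]
    bot <- sub_node_full[pruned_tree$edge[e, 2]]
    segs <- numeric(0); segnames <- character(0)
    nd <- bot
    while (nd != top) {
      fe <- edge_of_child[nd]
      em <- map$edge_maps[[fe]]
      segs <- c(em, segs)          # root-ward concatenation: prepend
      nd <- parent_full[nd]
    }
    # merge adjacent equal-state segments
    nm <- names(segs)
    if (length(segs) > 1) {
      keep <- c(TRUE, nm[-1] != nm[-length(nm)])
      grp <- cumsum(keep)
      segs <- tapply(segs, grp, sum)
      names(segs) <- nm[keep]
    }
    edge_maps[[e]] <- segs
  }
  node_states <- map$node_states[sub_node_full]
  structure(list(edge_maps = edge_maps, node_states = node_states,
                 states = map$states,
                 regimes = sort(unique(unlist(lapply(edge_maps, names)))),
                 edge = pruned_tree$edge, edge.length = pruned_tree$edge.length,
                 tree_ntip = n_sub),
            class = "regime_painting")
}
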