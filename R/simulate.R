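#' Simulate an ultrametric birth-death tree conditioned on tip count
#'
#' Wraps [ape::rphylo()] (birth-death conditioned on n extant tips), then
#' rescales to unit height by default so trait-model magnitudes (alpha,
#' sigma^2, r) are comparable across replicates.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param birth,death Speciation and extinction rates (death < birth).
#' @param seed Optional seed.
#' @param scale_height Rescale the tree to height 1 (default TRUE).
#' @return Ultrametric `phylo` with tips `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, birth = 1, death = 0, seed = NULL,
                          scale_height = TRUE) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (death >= birth) stop("death rate must be < birth rate")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth, death = death)
  if (scale_height) tr$edge.length <- tr$edge.length / tree_height(tr)
  tr
}

#' Simulate a discrete habitat history forward along a tree
#'
#' Forward Gillespie simulation of the continuous-time Markov chain defined
#' by Q down every branch from a fixed root state; returns both the full true
#' history (the same `stochastic_map` structure the mapping sampler produces)
#' and the induced tip states.
#'
#' @param tree `phylo`.
#' @param Q Generator matrix (dimnames = states, optional).
#' @param root_state State name or index at the root.
#' @param seed Optional seed.
#' @return List `map` (`stochastic_map`), `tip_states` (named character
#'   vector), `tip_priors` (unit-vector matrix for downstream Mk analyses).
#' @export
simulate_discrete_history <- function(tree, Q, root_state = 1, seed = NULL) {
  validate_rate_matrix(Q)
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(Q)
  states <- colnames(Q) %||% as.character(seq_len(k))
  if (is.character(root_state)) root_state <- match(root_state, states)
  stopifnot(root_state %in% seq_len(k))
  n <- length(tree$tip.label)
  node_state <- integer(n + tree$Nnode)
  root <- n + 1L
  node_state[root] <- root_state
  ne <- nrow(tree$edge)
  edge_maps <- vector("list", ne)
  events <- vector("list", ne)
  # preorder over edges: parents before children
  ord <- order(node_depths(tree)[tree$edge[, 1]])
  for (e in ord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_total <- tree$edge.length[e]
    s <- node_state[par]
    t0 <- 0
    seg_states <- s; seg_dur <- numeric(0); ev <- NULL
    repeat {
      rate <- -Q[s, s]
      dt <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (t0 + dt >= t_total) {
        seg_dur <- c(seg_dur, t_total - t0)
        break
      }
      t0 <- t0 + dt
      seg_dur <- c(seg_dur, dt)
      pvec <- pmax(Q[s, ], 0); pvec[s] <- 0
      nxt <- sample.int(k, 1, prob = pvec)
      ev <- rbind(ev, data.frame(time = t0, from = s, to = nxt, edge = e))
      s <- nxt
      seg_states <- c(seg_states, s)
    }
    edge_maps[[e]] <- stats::setNames(seg_dur, states[seg_states])
    events[[e]] <- ev
    node_state[ch] <- s
  }
  ev <- do.call(rbind, events[!vapply(events, is.null, TRUE)])
  if (is.null(ev)) ev <- data.frame(time = numeric(0), from = integer(0),
                                    to = integer(0), edge = integer(0))
  map <- structure(list(node_states = node_state, edge_maps = edge_maps,
                        events = ev, states = states, tree_ntip = n,
                        edge = tree$edge, edge.length = tree$edge.length),
                   class = "stochastic_map")
  tip_states <- stats::setNames(states[node_state[seq_len(n)]], tree$tip.label)
  tp <- matrix(0, n, k, dimnames = list(tree$tip.label, states))
  tp[cbind(seq_len(n), node_state[seq_len(n)])] <- 1
  list(map = map, tip_states = tip_states, tip_priors = tp)
}

#' Simulate habitat-linked categorical larval morphology
#'
#' Emulates a nominal character matrix whose category frequencies depend on a
#' discrete habitat regime: for each character a shared frequency vector and
#' one frequency vector per habitat are drawn from a flat Dirichlet; each
#' taxon's cell is sampled from the mixture
#' `(1 - beta) * shared + beta * habitat`, so `beta = 0` is habitat-free
#' noise and `beta = 1` maximal habitat linkage.
#'
#' @param tip_states Named character vector taxon -> habitat.
#' @param n_chars Number of characters.
#' @param levels Integer (shared level count) or vector to sample per
#'   character (default 2:4).
#' @param beta Habitat effect size in \[0, 1\].
#' @param seed Optional seed.
#' @return Character matrix taxa x characters (levels coded `l1`, `l2`, ...).
#' @export
simulate_categorical_morphology <- function(tip_states, n_chars = 89,
                                            levels = 2:4, beta = 0.9,
                                            seed = NULL) {
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (any(levels < 2)) stop("levels must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(tip_states)
  habs <- unique(tip_states)
  out <- matrix(NA_character_, length(taxa), n_chars,
                dimnames = list(taxa, paste0("char", seq_len(n_chars))))
  rdirich <- function(k) { g <- stats::rexp(k); g / sum(g) }
  for (ch in seq_len(n_chars)) {
    L <- if (length(levels) == 1) levels else sample(levels, 1)
    shared <- rdirich(L)
    per_hab <- lapply(habs, function(h) rdirich(L))
    names(per_hab) <- habs
    for (i in seq_along(taxa)) {
      pvec <- (1 - beta) * shared + beta * per_hab[[tip_states[i]]]
      out[i, ch] <- paste0("l", sample.int(L, 1, prob = pvec))
    }
  }
  out
}

#' Default habitat-state frequencies of the study clade
#'
#' Single-habitat specialist counts in the Aedini sample (container 117,
#' rock pool 20, crab hole 4, salt pool 23, ground pool 118), normalized.
#'
#' @return Named numeric vector over [habitat_states()].
#' @export
habitat_frequencies <- function() {
  counts <- c(container = 117, rock_pool = 20, crab_hole = 4,
              salt_pool = 23, ground_pool = 118)
  counts / sum(counts)
}

#' Generate a complete synthetic comparative dataset
#'
#' One call produces every input the analysis pipeline consumes, with shared
#' tip labels: an ultrametric tree, a true habitat history simulated under an
#' equal-rates Mk process from a ground-pool root, the habitat tip table, a
#' habitat-linked categorical morphology matrix, and (optionally) continuous
#' traits simulated under a trait model. The default shape mirrors the study
#' clade: 127 taxa, 5 habitat states, 89 characters with 2-4 levels.
#'
#' @param n_taxa Tips (default 127).
#' @param rate Equal Mk per-pair transition rate per unit tree height
#'   (default 0.1; with 5 states the total leaving rate is then 0.4, giving
#'   the handful of habitat shifts across the tree that a strongly conserved
#'   specialization shows).
#' @param root_state Root habitat (default "ground_pool").
#' @param n_chars,levels,beta Morphology generator settings.
#' @param birth,death Tree-shape parameters.
#' @param seed Master seed (fans out per component).
#' @return List of class `synthetic_dataset`: `tree`, `history`
#'   (`stochastic_map`), `tip_states`, `tip_priors`, `morphology`, `Q_true`,
#'   `config`.
#' @export
simulate_dataset <- function(n_taxa = 127, rate = 0.1,
                             root_state = "ground_pool", n_chars = 89,
                             levels = 2:4, beta = 0.9, birth = 1, death = 0,
                             seed = 1) {
  seeds <- derive_seeds(seed, c("tree", "history", "morphology"))
  tree <- simulate_tree(n_taxa, birth, death, seed = seeds[["tree"]])
  Q <- build_rate_matrix(rate, "ER", 5, habitat_states())
  hist <- simulate_discrete_history(tree, Q, root_state, seed = seeds[["history"]])
  morph <- simulate_categorical_morphology(hist$tip_states, n_chars, levels,
                                           beta, seed = seeds[["morphology"]])
  structure(list(tree = tree, history = hist$map, tip_states = hist$tip_states,
                 tip_priors = hist$tip_priors, morphology = morph, Q_true = Q,
                 config = list(n_taxa = n_taxa, rate = rate,
                               root_state = root_state, n_chars = n_chars,
                               levels = levels, beta = beta, birth = birth,
                               death = death, seed = seed)),
            class = "synthetic_dataset")
}
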