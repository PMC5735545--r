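#' Run the full comparative-convergence analysis
#'
#' Configuration-driven orchestration of the whole workflow: alignment
#' coverage QC, habitat rate-model selection and ancestral reconstruction,
#' stochastic mapping, morphospace construction (MCA), phylogenetic signal,
#' the simulation-null MANOVA, the Wheatsheaf index, multivariate model
#' comparison (BM/EB/OU1/OUM over sampled maps), and the simulation envelope.
#' Stages run in dependency order and fail fast with the stage name; a single
#' master seed fans out deterministically to per-stage child seeds.
#'
#' @param config A list, a path to a YAML file, or a `synthetic_dataset`
#'   (run with defaults). Recognized fields: `tree_file`/`tree`,
#'   `habitat_file`/`habitats` (taxon -> semicolon-separated habitat list) or
#'   `tip_priors`, `morphology_file`/`morphology` or `traits_file`/`traits`,
#'   `alignment_file` + `partition_file`, `outgroup`, `seed`, `stages`
#'   (character vector), `n_maps`, `n_keep`, `n_perm`, `n_sims`,
#'   `n_oum_maps`, `oum_keep_best`, `manova_nulls`, `focal_groups`,
#'   `alpha_structure`, `mk_models`, `n_restarts`, `output_dir`.
#' @return List of class `analysis_report` with one section per enabled
#'   stage, a config echo, and per-stage wall-clock seconds.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "synthetic_dataset")) {
    ds <- config
    config <- list(tree = ds$tree, tip_priors = ds$tip_priors,
                   morphology = ds$morphology, seed = ds$config$seed)
  }
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  # configuration errors before any compute
  for (f in c("tree_file", "habitat_file", "morphology_file", "traits_file",
              "alignment_file", "partition_file")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configuration error: ", f, " does not exist: ", cfg[[f]])
  }
  stages <- cfg[["stages"]] %||% c("coverage_qc", "asr", "mapping", "mca", "signal",
                              "manova", "wheatsheaf", "models", "envelope")
  if (is.null(cfg[["seed"]])) stop("configuration error: seed required")
  seeds <- derive_seeds(cfg[["seed"]],
                        c("mapping", "signal", "manova", "wheatsheaf",
                          "models", "envelope", "mk"))
  report <- list(config = cfg[setdiff(names(cfg), c("tree", "tip_priors",
                                                    "morphology", "traits"))],
                 seed = cfg[["seed"]], timings = list())
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  tree <- if (!is.null(cfg[["tree"]])) cfg[["tree"]] else read_newick(cfg[["tree_file"]])
  validate_phylogeny(tree)

  if ("coverage_qc" %in% stages && !is.null(cfg[["alignment_file"]])) {
    report$coverage <- timed("coverage_qc", {
      aln <- read_alignment(cfg[["alignment_file"]])
      parts <- if (!is.null(cfg[["partition_file"]])) read_partitions(cfg[["partition_file"]])
      cov <- coverage_stats(aln, parts)
      tau <- tryCatch(coverage_branchlength_tau(tree, aln),
                      error = function(e) NULL)
      list(totals = cov$totals, per_taxon = cov$per_taxon, tau = tau)
    })
  }

  if (!is.null(cfg[["outgroup"]])) {
    og <- normalize_labels(cfg[["outgroup"]])
    tree <- prune_to(tree, setdiff(tree$tip.label, og))
  }

  tip_priors <- if (!is.null(cfg[["tip_priors"]])) cfg[["tip_priors"]] else {
    hab <- cfg[["habitats"]]
    if (is.null(hab) && !is.null(cfg[["habitat_file"]])) {
      tab <- utils::read.delim(cfg[["habitat_file"]], sep = "\t",
                               stringsAsFactors = FALSE)
      hab <- stats::setNames(tab$habitat, tab$taxon)
    }
    if (is.null(hab)) NULL else make_tip_priors(hab)
  }
  if (!is.null(tip_priors)) {
    unmatched <- setdiff(tree$tip.label, rownames(tip_priors))
    if (length(unmatched))
      stop("taxon-label mismatch between tree and habitat table: ",
           paste(unmatched, collapse = ", "))
    tip_priors <- tip_priors[intersect(rownames(tip_priors), tree$tip.label), ,
                             drop = FALSE]
  }

  best_mk <- NULL
  if ("asr" %in% stages && !is.null(tip_priors)) {
    report$asr <- timed("asr", {
      cmp <- compare_mk_models(tree, tip_priors,
                               kinds = cfg[["mk_models"]] %||% c("ER", "SYM", "ARD"),
                               n_restarts = cfg[["n_restarts"]] %||% 3,
                               seed = seeds[["mk"]])
      best_mk <- attr(cmp, "fits")[[cmp$kind[1]]]
      asr <- marginal_asr(tree, tip_priors, best_mk$Q)
      root <- length(tree$tip.label) + 1L
      list(model_table = cmp, best_kind = cmp$kind[1], Q = best_mk$Q,
           node_probs = asr$node_probs,
           root_probs = asr$node_probs[as.character(root), ])
    })
  }

  maps <- NULL
  if ("mapping" %in% stages && !is.null(best_mk)) {
    report$mapping <- timed("mapping", {
      maps <- sample_stochastic_maps(tree, tip_priors, best_mk$Q,
                                      n_maps = cfg[["n_maps"]] %||% 1000,
                                      seed = seeds[["mapping"]])
      sm <- summarize_maps(maps)
      root <- length(tree$tip.label) + 1L
      list(n_maps = sm$n_maps,
           root_probs = sm$node_probs[as.character(root), ],
           mean_transitions = sm$mean_transitions,
           node_probs = sm$node_probs)
    })
  }

  traits <- NULL
  if (!is.null(cfg[["traits"]])) traits <- as.matrix(cfg[["traits"]])
  if (is.null(traits) && !is.null(cfg[["traits_file"]])) {
    tt <- utils::read.delim(cfg[["traits_file"]], row.names = 1)
    traits <- as.matrix(tt)
  }
  morph <- cfg[["morphology"]]
  if (is.null(morph) && !is.null(cfg[["morphology_file"]])) {
    morph <- as.matrix(utils::read.csv(cfg[["morphology_file"]], row.names = 1))
  }
  if ("mca" %in% stages && !is.null(morph)) {
    report$mca <- timed("mca", {
      res <- run_mca(morph, n_keep = cfg[["n_keep"]] %||% 5)
      # orient: positive dimension-1 mean for the container group when known
      if (!is.null(tip_priors)) {
        cont <- rownames(tip_priors)[tip_priors[, "container"] == 1]
        cont <- intersect(cont, rownames(res$row_coords))
        if (length(cont) >= 2) res <- orient_dimensions(res, cont, sign = 1)
      }
      traits <- res$traits
      list(eigenvalues = res$eigenvalues, percent = res$percent,
           kept = ncol(res$traits), J = res$J, Q = res$Q)
    })
  }

  if (is.null(traits)) {
    report$class <- "analysis_report"
    class(report) <- "analysis_report"
    return(report)
  }
  rownames(traits) <- normalize_labels(rownames(traits))
  ctree <- if (setequal(tree$tip.label, rownames(traits))) tree
           else prune_to(tree, intersect(tree$tip.label, rownames(traits)))

  groups <- NULL
  if (!is.null(tip_priors)) {
    # strict single-habitat assignment for grouping; multi-habitat taxa keep
    # their highest-prior state
    groups <- apply(tip_priors[ctree$tip.label, , drop = FALSE], 1,
                    function(v) colnames(tip_priors)[which.max(v)])
  }

  if ("signal" %in% stages) {
    report$signal <- timed("signal", {
      lapply(stats::setNames(seq_len(ncol(traits)), colnames(traits) %||%
                               paste0("Dim", seq_len(ncol(traits)))),
             function(j) {
               r <- blomberg_k(ctree, stats::setNames(traits[, j], rownames(traits)),
                               n_perm = cfg[["n_perm"]] %||% 1000,
                               seed = seeds[["signal"]] + j)
               r[c("K", "p")]
             })
    })
  }

  if ("manova" %in% stages && !is.null(groups)) {
    report$manova <- timed("manova", {
      # the test needs >= 2 taxa per group: habitats with a single
      # representative are set aside for this stage only
      tab <- table(groups)
      keep_g <- names(tab)[tab >= 2]
      taxa_g <- names(groups)[groups %in% keep_g]
      mtree <- if (length(taxa_g) < length(groups)) prune_to(ctree, taxa_g) else ctree
      nulls <- cfg[["manova_nulls"]] %||% c("BM", "EB", "OU1")
      lapply(stats::setNames(nulls, nulls), function(nk)
        phylo_manova(mtree, traits[taxa_g, , drop = FALSE], groups[taxa_g],
                     null = nk, n_sims = cfg[["n_sims"]] %||% 1000,
                     seed = seeds[["manova"]])[c("lambda", "F", "p", "n_sims")])
    })
  }

  if ("wheatsheaf" %in% stages && !is.null(groups)) {
    report$wheatsheaf <- timed("wheatsheaf", {
      fgs <- cfg[["focal_groups"]] %||% c("container", "ground_pool")
      out <- list()
      for (fg in fgs) {
        focal <- names(groups)[groups == fg]
        if (length(focal) >= 2 && length(focal) < length(groups)) {
          out[[fg]] <- wheatsheaf(ctree, traits[, 1, drop = FALSE], focal,
                                  n_boot = cfg[["n_sims"]] %||% 1000,
                                  seed = seeds[["wheatsheaf"]])[c("w", "p", "focal_n")]
        }
      }
      out
    })
  }

  fits <- NULL
  if ("models" %in% stages) {
    report$models <- timed("models", {
      astr <- cfg[["alpha_structure"]] %||% "spd"
      nres <- cfg[["n_restarts"]] %||% 3
      fits <- list(BM = fit_model(ctree, traits, "BM"),
                    EB = fit_model(ctree, traits, "EB"),
                    OU1 = fit_model(ctree, traits, "OU1",
                                    alpha_structure = astr,
                                    n_restarts = nres, seed = seeds[["models"]]))
      if (!is.null(maps)) {
        oums <- fit_oum_over_maps(ctree, traits, maps, full_tree = tree,
                                  n_sample = cfg[["n_oum_maps"]] %||% 100,
                                  keep_best = cfg[["oum_keep_best"]] %||% 3,
                                  alpha_structure = astr, n_restarts = nres,
                                  seed = seeds[["models"]])
        names(oums) <- paste0("OUM", seq_along(oums))
        fits <- c(fits, oums)
      }
      tab <- akaike_weights(fits)
      list(table = tab, alpha_structure = astr,
           oum_cumulative_weight = sum(tab$weight[grepl("^OUM", tab$model)]))
    })
  }

  if ("envelope" %in% stages && !is.null(fits)) {
    report$envelope <- timed("envelope", {
      best_name <- report$models$table$model[1]
      best <- fits[[best_name]]
      env <- envelope_check(ctree, traits, best,
                            n_sims = cfg[["n_sims"]] %||% 1000,
                            seed = seeds[["envelope"]], dims = 1)
      list(best_model = best_name, pass_fraction = env$pass_fraction,
           n_sims = env$n_sims,
           n_outside = sum(!env$table$within_2sd))
    })
  }

  class(report) <- "analysis_report"
  if (!is.null(cfg[["output_dir"]])) write_report(report, cfg[["output_dir"]])
  report
}

#' Serialize an analysis report to JSON (plus TSV tables)
#'
#' @param report `analysis_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Path to the JSON report, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  ser <- report
  # matrices serialize as data frames with stable row keys
  flat <- function(x) {
    if (is.matrix(x)) return(as.data.frame(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, flat))
    x
  }
  jsonlite::write_json(flat(unclass(ser)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(report$models))
    utils::write.table(report$models$table, file.path(dir, "model_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate an analysis report against the shipped schema
#'
#' Lightweight structural validation: checks the required top-level keys and
#' per-stage required fields declared in the JSON schema shipped under
#' `inst/schema/report-schema.json`.
#'
#' @param report `analysis_report` or path to a report JSON.
#' @return TRUE invisibly, or an error describing the violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "mosqconv"))
  req <- unlist(schema$required)
  miss <- setdiff(req, names(report))
  if (length(miss)) stop("report missing required keys: ", paste(miss, collapse = ", "))
  for (sec in names(schema$properties)) {
    if (!is.null(report[[sec]]) && !is.null(schema$properties[[sec]]$required)) {
      miss <- setdiff(unlist(schema$properties[[sec]]$required), names(report[[sec]]))
      if (length(miss))
        stop("report section '", sec, "' missing: ", paste(miss, collapse = ", "))
    }
  }
  invisible(TRUE)
}
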