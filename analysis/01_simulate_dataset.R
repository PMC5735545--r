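#!/usr/bin/env Rscript
# Stage 1: generate the synthetic comparative dataset the rest of the
# workflow analyses. Shape mirrors the study clade: 127 taxa, 5 larval
# habitats (ground-pool root, conserved Mk evolution), 89 nominal larval
# characters whose category frequencies depend on habitat (beta = 0.9).
suppressMessages(library(mosqconv))

SEED <- 2026
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- simulate_dataset(seed = SEED)
writeLines(write_newick(ds$tree), file.path(out, "tree.nwk"))
write.table(data.frame(taxon = names(ds$tip_states),
                       habitat = unname(ds$tip_states)),
            file.path(out, "habitats.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.csv(as.data.frame(ds$morphology), file.path(out, "morphology.csv"))
# the planted truth, for later comparison
writeLines(jsonlite::toJSON(list(
  seed = SEED, root_state = ds$config$root_state,
  mk_rate = ds$config$rate, beta = ds$config$beta,
  n_events = nrow(ds$history$events),
  habitat_counts = as.list(table(ds$tip_states))), auto_unbox = TRUE,
  pretty = TRUE), file.path(out, "truth.json"))

cat("Simulated", length(ds$tree$tip.label), "taxa;",
    nrow(ds$history$events), "habitat transitions along the tree;",
    "tip habitat counts:\n")
print(table(ds$tip_states))
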