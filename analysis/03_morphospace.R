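#!/usr/bin/env Rscript
# Stage 3: morphospace. Multiple correspondence analysis of the nominal
# larval characters; keeps the first five dimensions as the continuous trait
# matrix and orients dimension signs so container taxa score positive.
suppressMessages(library(mosqconv))

hab <- read.delim("results/data/habitats.tsv")
morph <- as.matrix(read.csv("results/data/morphology.csv", row.names = 1))
dir.create("results/morphospace", recursive = TRUE, showWarnings = FALSE)

mca <- run_mca(morph, n_keep = 5)
cont <- hab$taxon[hab$habitat == "container"]
mca <- orient_dimensions(mca, cont, sign = 1)

write.table(data.frame(dim = seq_along(mca$eigenvalues),
                       inertia = mca$eigenvalues,
                       percent = round(mca$percent, 3)),
            "results/morphospace/inertia.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(round(mca$traits, 6), "results/morphospace/scores.tsv",
            sep = "\t", quote = FALSE)

cat("Total categories J =", mca$J, "over Q =", mca$Q, "characters\n")
cat(sprintf("Dimension 1 explains %.2f%%, dimension 2 %.2f%% of inertia\n",
            mca$percent[1], mca$percent[2]))
cat(sprintf("First five dimensions: %.1f%% cumulative\n",
            sum(mca$percent[1:5])))
grp <- setNames(hab$habitat, hab$taxon)[rownames(mca$traits)]
cat("Mean dimension-1 score, container vs ground pool:",
    round(mean(mca$traits[grp == "container", 1]), 3), "vs",
    round(mean(mca$traits[grp == "ground_pool", 1]), 3), "\n")
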