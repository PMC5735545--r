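# mosqconv

Comparative-phylogenetics analyses of how larval habitat specialization and
larval morphology evolved in Aedini mosquitoes — the tribe containing
*Aedes aegypti* and *Aedes albopictus*, whose use of small container habitats
(treeholes, leaf axils, tires) underlies their human-aided global spread.
The package is for evolutionary biologists who want to ask, on a
time-calibrated phylogeny with a discrete habitat character and a
morphological character matrix: was container dwelling ancestral or
repeatedly derived, and did larval phenotype converge with habitat?

## What it computes

* **Habitat evolution.** Mk models of the five-state habitat character
  (container, rock pool, crab hole, salt pool, ground pool) with ER/SYM/ARD
  rate constraints compared by AICc weight; marginal ancestral-state
  reconstruction; stochastic character mapping by exact endpoint-conditioned
  uniformization, summarized into node posterior probabilities and
  transition counts. Multi-habitat taxa enter as equal-mass tip priors.
* **Morphospace.** Indicator-matrix multiple correspondence analysis (MCA)
  of nominal larval characters: principal inertias λ (with the identity
  Σλ = J/Q − 1), percent variance, row scores; the first dimensions become
  the continuous trait matrix, with axis signs anchored so container taxa
  score positive.
* **Convergence statistics.** Blomberg's K (K = 1 under Brownian motion)
  with permutation tests; a phylogenetically informed MANOVA whose null
  distribution is *simulated* under a fitted evolutionary model — BM, EB,
  OU1, or a user-supplied fit such as the best multi-optimum OU model; the
  Wheatsheaf index w = mean penalized phenotypic distance over all pairs /
  mean over focal pairs, with distances penalized by phylogenetic
  relatedness and significance by bootstrap.
* **Trait models.** Multivariate BM, early burst (rate ∝ e^{rt}, r ≤ 0),
  single-optimum OU, and multi-optimum OU over habitat regimes painted by
  stochastic maps (Θ one optimum per habitat, root fixed at the root-regime
  optimum, A and R symmetric positive-definite); ML fits with GLS-profiled
  optima, AICc and Akaike weights, exact Gaussian simulation, and a
  ±2 SD simulation envelope for model validation.
* **Synthetic data.** Birth–death trees, forward-simulated habitat
  histories, and habitat-linked categorical morphology (effect size β),
  shaped like the study clade (127 taxa, 89 characters, 5 habitats), so the
  entire workflow runs with no external files.

## Worked example

```r
library(mosqconv)

ds <- simulate_dataset(n_taxa = 60, seed = 42)   # tree + habitats + morphology
rep <- run_pipeline(list(
  tree = ds$tree, tip_priors = ds$tip_priors, morphology = ds$morphology,
  seed = 42, n_maps = 300, n_keep = 3, n_perm = 500, n_sims = 300,
  n_oum_maps = 4, oum_keep_best = 2, alpha_structure = "diagonal",
  n_restarts = 1, manova_nulls = "BM"))

round(rep$mapping$root_probs, 3)
#>   container   rock_pool   crab_hole   salt_pool ground_pool
#>       0.000       0.003       0.003       0.000       0.993
rep$asr$best_kind
#> [1] "ER"
round(rep$mca$percent[1:3], 2)
#> [1] 8.85 5.68 3.64
sapply(rep$signal, function(s) round(s$K, 2))
#> Dim1 Dim2 Dim3
#> 0.59 0.27 0.12
rep$manova$BM$p
#> [1] 0.003322259
print(rep$models$table[, c("model", "aicc", "weight")], digits = 3)
#>      model aicc   weight
#> OUM1  OUM1 -162 6.25e-01
#> OUM2  OUM2 -161 3.75e-01
#> OU1    OU1   58 1.09e-48
#> BM      BM  134 3.05e-65
#> EB      EB  136 9.93e-66
rep$envelope$pass_fraction
#> [1] 0.9333333
```

Reading the output: the planted ground-pool root is recovered with posterior
0.993 from 300 stochastic maps under the winning equal-rates model; MCA
dimension 1 carries 8.9% of the inertia and separates habitats (the MANOVA
rejects a group-blind BM null, p ≈ 0.003); the two habitat-linked OUM fits
(regimes from different sampled maps) share essentially all Akaike weight,
more than 10^48 : 1 over the best habitat-blind model, as they should for
data generated with habitat-dependent optima; and 93% of taxa (56 of 60)
fall inside the best model's ±2 SD simulation envelope on dimension 1.

The `analysis/` directory holds the same workflow as five numbered driver
scripts (simulate → habitat reconstruction → morphospace → signal &
convergence → model comparison), each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_dataset.R
Rscript analysis/02_habitat_reconstruction.R
Rscript analysis/03_morphospace.R
Rscript analysis/04_signal_and_convergence.R
Rscript analysis/05_model_comparison.R
```

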