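---
title: "Methods: convergent evolution of larval habitat and morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergent evolution of larval habitat and morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mosqconv` implements a comparative-phylogenetics workflow for asking two
linked questions about Aedini mosquitoes: did specialization on container
larval habitats (treeholes, leaf axils, tires — the trait behind the global
spread of *Aedes* disease vectors) evolve repeatedly from an ancestral
ground-pool habit, and did larval morphology converge along with it? The
package provides the discrete-character machinery (Mk models, ancestral
states, stochastic maps), the morphospace construction (MCA), the
convergence statistics (Blomberg's K, a simulation-null phylogenetic MANOVA,
the Wheatsheaf index), and multivariate trait models (BM, EB, OU), plus a
synthetic-data module so the entire analysis runs and is testable without any
external data. This vignette records the models, the defaults, and the design
choices a maintainer would want to know about.

## Habitat evolution: Mk models, ancestral states, stochastic maps

The habitat character has five states: container, rock pool, crab hole, salt
pool, ground pool. Its evolution is modeled as a continuous-time Markov chain
with generator $Q$ under three constraint families: equal rates (ER, 1 free
rate), symmetric (SYM, 10), and all-rates-different (ARD, 20). The likelihood
is computed by Felsenstein pruning with per-branch transition matrices
$e^{Qt}$ (one eigendecomposition per likelihood evaluation, with a
scaling-and-squaring fallback when the eigenbasis is ill-conditioned) and
per-node rescaling against underflow. Taxa occupying several habitats enter
as tip vectors with equal mass on each occupied state; a taxon with unknown
habitat gets a uniform vector. Under this likelihood, treating multi-habitat
taxa as priors or as observed ambiguity is mathematically identical.

Choices the original tools leave implicit, fixed here:

* **Root prior**: flat over the five states (a stationary-prior option is
  exposed via the `root_prior` argument). The flat prior matches the
  equal-probability convention used for uncertain tips.
* **Optimization**: rates in log space, bounds $[10^{-9}, 10^3]$ per unit
  branch length, L-BFGS-B from a moment-based start (observed states / total
  tree length) plus random restarts (default 5).
* **AICc** sample size = number of tips.
* Rate families with more parameters than the tip count can support
  ($K + 1 \ge n$) are dropped from a comparison with a warning rather than
  producing an undefined AICc.

Marginal ancestral states come from the standard two-pass (upward pruning,
downward conditioning) algorithm; each node's vector sums to 1.

**Stochastic maps** are sampled with $Q$ fixed at its ML estimate (the
"empirical" workflow; no hyperprior on $Q$). Node states are drawn from their
conditionals given tip data, then each branch history is drawn *exactly*,
conditional on its endpoints, by endpoint-conditioned uniformization:
dominating rate $\Omega = \max_i |Q_{ii}|$, the number of dominated-chain
jumps drawn from its exact conditional distribution (cached powers of
$I + Q/\Omega$), jump times as uniform order statistics, and the jump chain
by forward-backward filtering. This sampler needs no rejection loop and is
reproducible bit-for-bit under a seed; the independent check in the test
suite is a forward-simulation/quadrature oracle for conditional transition
counts. Node posteriors from $n$ maps converge to the marginal
reconstruction at the Monte-Carlo rate $\sqrt{p(1-p)/n}$, which is how the
map counts in the tests were sized (20,000 maps keep 3 SE under the 0.02
comparison tolerance).

## Morphospace: indicator-matrix MCA

The nominal larval-character matrix is expanded to a 0/1 indicator, scaled
to correspondence proportions, centered by the rank-one margin product,
whitened by row and column masses, and decomposed by SVD. Principal inertias
are squared singular values and satisfy $\sum_d \lambda_d = J/Q - 1$ ($J$
categories, $Q$ characters) — an identity asserted in the tests. No
Benzécri/Greenacre correction is applied: the raw indicator inertias are what
the downstream percent-variance statements refer to. Missing cells become an
extra "missing" level per character by default (keeping all taxa), with a
complete-case option; both modes are exposed because published analyses
rarely state their convention. Because an SVD axis sign is arbitrary while
the narrative ("container taxa score positive on dimension 1") is not,
`orient_dimensions()` fixes each axis sign against an anchor taxon or group
mean; the pipeline anchors the container-group mean positive on every
dimension. Ordered characters are excluded by listing them in the config, as
ordinal structure is not representable in a plain MCA.

## Multivariate trait models

Let $X$ be the $n \times p$ matrix of kept morphospace dimensions. All four
models are Gaussian on the stacked $np$-vector:

* **BM**: covariance $C \otimes R$, $C$ the shared root-to-MRCA path-length
  matrix, $R$ the SPD diffusion matrix; root mean $\mu_0$ free.
* **EB**: BM with rate decaying as $e^{rt}$, $r \le 0$; $C$ entries $s$
  become $(e^{rs}-1)/r$. $r = 0$ reproduces BM exactly (asserted), so the
  nesting inequality $\ell_{EB} \ge \ell_{BM}$ holds by construction.
* **OU1 / OUM**: mean-reverting process with SPD selection matrix $A$ and
  one optimum, or one optimum per habitat regime painted on the tree. With
  $A = U D U^\top$ and an ultrametric tree, tip-covariance blocks in the
  eigenbasis of $A$ are
  $\tilde R_{kl}\, e^{-(d_k+d_l)(T-s)} \frac{1-e^{-(d_k+d_l)s}}{d_k+d_l}$,
  so the $np \times np$ covariance reduces to $p^2$ scalar kernels of the
  MRCA-depth matrix. The root state is **fixed at the root-regime optimum**
  (no root variance, not a free parameter) — the recommended convention for
  trees of extant taxa only. A corollary worth knowing: under OU1 the tip
  mean is exactly $\theta$ for every tip.

Fitting: BM and EB are profiled in closed form (GLS root mean and diffusion
MLE given the path matrix; EB adds a 1-D search over $r \in [-20/T, 0]$).
OU models optimize the log-Cholesky factors of $A$ and $R$ (Nelder-Mead up
to 12 parameters, BFGS beyond), with the optima profiled out by GLS at every
evaluation — this is what makes 5-regime OUM fits tractable, since only the
covariance parameters are searched. $A$ is SPD by default with a
diagonal-only option (`alpha_structure`); outputs record which was used.
Initial values are moment-based ($R$ from the BM fit, $\alpha$ from half the
inverse tree height) with perturbed restarts. Tree geometry (MRCA depths,
painting segment tables) is cached per fit. OUM regime paintings come from
sampled stochastic maps: a random subsample (100 by default in
`fit_oum_over_maps()`) is fitted one model per map and the best few by AICc
(3 by default) carried into the final comparison; maps after the first are
warm-started from the first converged fit, since paintings differ only in
regime layout. AICc uses $n_{obs} = n \times p$. Model weights are standard
Akaike weights; the test suite checks them against a published comparison
table used as input.

Simulation (`simulate_traits()`) is exact Gaussian sampling from the model
mean and covariance, not branch-wise discretization; a zero diffusion matrix
is allowed as a degenerate boundary for testing. The envelope validation
simulates from the fitted model and flags per taxon and dimension whether the
observed value sits within the simulated mean ± 2 SD; under a correct model
about 95.4% of values should pass.

## Convergence statistics

**Blomberg's K** follows the ratio-of-MSE definition: the tip-level mean
squared deviation from the GLS phylogenetic mean over the GLS mean squared
error under the tree covariance, standardized by the analytic BM expectation
of that ratio, so $K = 1$ under BM and $K > 1$ means variance distributed
among clades. The permutation test shuffles tip labels; all empirical
p-values in the package use the add-one convention
$p = (1 + \#\{stat_{perm} \ge stat_{obs}\})/(1 + n_{perm})$, which avoids
$p = 0$ and uses $\ge$ for ties.

**Phylogenetic MANOVA.** The observed statistic is the ordinary one-way
MANOVA Wilks' $\Lambda$ of traits on habitat groups, compared through its
Rao F approximation (larger F = stronger group effect). The phylogeny enters
only through the null: trait matrices simulated on the tree under a fitted
evolutionary model, the statistic recomputed per simulation. For bare model
kinds (BM, EB, OU1) the null parameters are fitted to the observed traits
*ignoring groups*; passing a fitted OUM instead retains its habitat-linked
optima, which turns the test around into a plausibility check of that model
(a non-significant p then says the model generates data like the observed).
Habitat groups with fewer than two taxa cannot contribute a within-group
covariance and are set aside for this test only.

**Wheatsheaf index.** The strength-of-convergence index is a ratio of
penalized phenotypic distances. The methods paper that defines it does not
restate its penalization kernel in the seed literature available here, so the
package fixes one and documents it: traits are z-scored per dimension,
Euclidean distances $E_{ij}$ are penalized multiplicatively by phylogenetic
relatedness, $q_{ij} = E_{ij}(1 + \rho_{ij})$ with $\rho_{ij}$ the shared
root-to-MRCA fraction of tree height, so phenotypic similarity between close
relatives counts for less; then
$w = \overline{q}_{\text{all pairs}} / \overline{q}_{\text{focal pairs}}$.
$w = 1$ exactly when the focal group is the whole sample; large $w$ with a
small bootstrap p (random focal sets of the same size, add-one) indicates a
focal group far tighter than chance — which may be convergence or
conservation; the index cannot distinguish them, so focal groups must be
chosen a priori. By default focal groups contain strict specialists only;
multi-habitat taxa stay in the background set.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every downstream number refers to:

* 127 taxa (the count with both molecular and morphological data in the
  motivating study) on a unit-height birth-death tree conditioned on the tip
  count (pure birth by default). Unit height makes $\alpha$, $\sigma^2$ and
  $r$ magnitudes comparable across replicates.
* Habitat evolved forward (Gillespie) under ER with per-pair rate 0.1 per
  unit height from a ground-pool root. With five states that is a total
  leaving rate of 0.4 — a handful of transitions across the whole tree,
  matching the strongly conserved specialization the study clade shows
  (decisive root support, K above 1, few container origins). The paper never
  prints its fitted rate, so this is the package's own calibration of
  "realistic", fixed once.
* 89 nominal characters with 2-4 levels. Each character draws a shared
  frequency vector and one per habitat (flat Dirichlet); a cell samples from
  $(1-\beta)\,\text{shared} + \beta\,\text{habitat}$. $\beta = 0$ gives
  habitat-free noise (the null-calibration setting); $\beta = 0.9$, the
  default, produces the clear container/ground-pool separation on MCA
  dimension 1 that the real matrix shows.

What the generator deliberately does **not** emulate: phylogenetic
autocorrelation of morphology *within* a habitat class beyond what the
habitat history induces, missing data, ordered characters, GenBank-style
missing-marker structure, or multi-habitat taxa. Passing tests therefore
demonstrate that the machinery recovers planted structure of this kind; they
do not certify behavior on data whose noise violates these simplifications.

## Numerical and reproducibility choices

* Ultrametricity is declared at relative tolerance $10^{-6}$ by default
  (penalized-likelihood calibrated trees are only numerically ultrametric);
  OU fitting accepts trees up to $10^{-3}$ relative spread.
* Tip labels are matched after trimming whitespace and unifying spaces with
  underscores, the two conventions newick files actually mix.
* "Absent" alignment characters are `-`, `?`, `N` (case-insensitive); a
  marker is present for a taxon if at least one non-absent site falls in its
  partition interval.
* Every stochastic operation takes a seed; the pipeline derives per-stage
  child seeds deterministically from one master seed, so toggling one stage
  never perturbs another's draws. Identical config + seed reproduces reports
  bit-for-bit (timings aside).
* Degenerate inputs fail fast with named errors: zero-height trees, constant
  traits (all covariance models become singular), groups below two taxa,
  non-PD $R$ or $A$, paintings missing a regime optimum.

## Problem sizes used in tests and the acceptance script

The full synthetic study (127 taxa, 89 characters, 1000 maps, 1000
permutations/bootstraps, 500-1000 null simulations, OUM over 6 sampled maps
with diagonal $A$ and warm starts) is what `scripts/acceptance.R` and the
`analysis/` drivers run. Property checks use sizes chosen by Monte-Carlo
arithmetic rather than maximal counts: e.g. 400 replicates bound the type-I
error estimate's SE near 0.011 against the [0.025, 0.075] acceptance band;
recovery tests use 48-150 taxa, 2 trait dimensions, and single-map OUM fits,
which preserve the estimator geometry at a fraction of the cost of the full
protocol. These are the package's own choices of simulation size and are
fixed in the test files.

## Known limitations

* No hidden-rate (covarion) models, joint reconstructions, or Bayesian
  sampling of $Q$; no measurement-error term or non-ultrametric OU
  extensions; regimes always come from habitat maps, never from
  reversible-jump detection.
* The Wheatsheaf kernel is the package's documented choice; numerical
  comparability with other implementations depends on their kernel.
* OUM AICc values depend on optimizer convergence in a 20+-parameter space;
  the comparison table's *ordering* and weights are robust in testing, exact
  AICc values carry optimizer tolerance.
* MCA handles nominal characters only; ordered characters must be excluded
  by configuration.
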