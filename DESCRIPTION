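Package: mosqconv
Title: Convergent Evolution of Larval Habitat and Morphology in Aedini Mosquitoes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetics toolkit for studying the repeated
    evolution of container-habitat use and associated larval morphology in
    Aedini mosquitoes. Implements Mk discrete-character likelihoods with
    equal-rate, symmetric and all-rates-different constraints, marginal
    ancestral-state reconstruction and stochastic character mapping by exact
    endpoint-conditioned uniformization; multiple correspondence analysis of
    nominal morphological matrices; Blomberg's K with permutation tests; a
    phylogenetic MANOVA whose null distributions are simulated under fitted
    Brownian-motion, early-burst or Ornstein-Uhlenbeck models; the Wheatsheaf
    convergence index; and multivariate BM/EB/OU trait models over
    regime-painted trees with AICc comparison, exact Gaussian simulation and
    simulation-envelope validation. A synthetic-data module generates
    birth-death trees, discrete habitat histories and habitat-linked
    categorical morphology so the entire analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante
Config/testthat/edition: 3
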