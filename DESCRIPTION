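Package: chronodate
Title: Bayesian Relaxed-Clock Node Dating with Sequential Calibrations and
    Gene-Verticality Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian molecular-clock node dating on fixed rooted topologies
    with fossil calibrations expressed as soft bounds, a birth-death prior on
    node ages, strict / independent-lognormal / autocorrelated branch-rate
    models, and both exact (pruning) and approximate (quadratic surface)
    likelihoods. Implements the two-step sequential calibration strategy
    (parametric densities fitted to first-step posterior node ages and imposed
    as second-step priors), clock-model selection by stepping-stone marginal
    likelihoods and Bayes factors, delta-log-likelihood gene-verticality
    screening with gene-removal and sliding-window protocols, and
    genomic-content convergence and association analyses (Manhattan and
    MinHash/mash distances, non-metric MDS, a normalized-dissimilarity
    permutation test, and a Fisher / Pearson / phylogenetic-signal battery
    with Benjamini-Hochberg correction). Ships a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    yaml,
    phytools,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
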