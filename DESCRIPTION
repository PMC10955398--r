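Package: geophylocausal
Title: Diachronic Causal Models for Environmental Effects on Traits Evolving
    on Geo-Referenced Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for testing whether an environmental variable (such as
    specific humidity) causally affects a cultural or linguistic trait (such
    as the number of lexical tones) evolving along a time-calibrated,
    geographically annotated phylogeny.  Provides geo-phylogenetic tree
    structures with per-node ages and locations, synthetic data generators
    (Yule trees, Brownian dispersal, smooth space-time environment fields,
    null and environment-driven trait histories), exact-Gaussian Brownian
    ancestral state reconstruction with root fossilisation, Pagel's lambda,
    tensor-product spline interpolation of gridded climate fields,
    diagnostics for the type-I error inflation that tree-structured data
    induce in naive cross-sectional regressions, node-importance
    perturbation analysis, correlated-evolution tests (Pagel's discrete
    dependent/independent CTMC test and the bivariate Brownian correlation),
    and two Bayesian diachronic causal models of ancestor-to-descendant
    trait change (a linear-confound variant and a Gaussian-process variant)
    with Savage-Dickey Bayes factors and PSIS-LOO expected log predictive
    density comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    mgcv,
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
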