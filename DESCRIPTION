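Package: macroevo
Title: Regime-Painted Gaussian Trait Evolution, Disparity and Model-Selection
    Power on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of continuous trait evolution on
    time-calibrated phylogenies. Fits an eleven-scenario suite of Gaussian
    trait-evolution models (Brownian motion, Ornstein-Uhlenbeck, early burst,
    time-slice rate shift, ecological release, and multi-rate/multi-optimum
    variants over regime paintings of the tree) by maximum likelihood with AICc
    comparison across a posterior tree sample; computes disparity-through-time
    curves and the MDI statistic with Brownian simulation nulls; runs Monte
    Carlo (parametric bootstrap) model-selection power tests; performs Mk
    marginal ancestral-state reconstruction to paint discrete regimes; and
    provides the trait/climate data-preparation chain (log range midpoints,
    phylogenetic-eigenvector-augmented imputation, independent contrasts,
    phylogenetic GLS size correction, phylogenetic PCA) together with seeded
    synthetic-data generators and an end-to-end study pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
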