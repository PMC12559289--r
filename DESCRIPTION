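Package: bartsdm
Title: Probit Bayesian Additive Regression Trees for Species Distribution
    Modelling with Simulation-Based Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and stress-testing species distribution
    models (SDMs) on gridded landscapes. Implements a probit Bayesian
    additive regression trees (BART) classifier from first principles
    (sum-of-trees Metropolis-within-Gibbs sampler with the standard
    depth-penalising tree prior and conjugate leaf values), a
    virtual-species simulator built on a Matern Gaussian random field with
    AR(1) temporal dynamics, replicate presence/absence and pseudo-absence
    sampling protocols, MaxEnt-style and generalized additive model
    baselines, confusion-matrix validation with Youden-index cutoffs and
    k-fold cross-validation, and a habitat-projection pipeline with
    covariate standardization, native-range versus suitable-habitat model
    variants, change maps, richness stacking and percentage-change
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    mgcv,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
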