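Package: mooddsem
Title: Dynamic Structural Equation Models for Weekly Mood and Sleep Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing intensive longitudinal panels of weekly
    self-reported mood and insomnia symptoms in bipolar disorder. Implements
    questionnaire scoring for the QIDS-SR16 (with the insomnia subscale split
    out) and the ASRM, a SummarizedExperiment-based panel container with
    eligibility filtering, a multilevel bivariate AR(1) dynamic structural
    equation model with person-specific means, inertias, cross-lagged effects,
    log innovation variances and linear trends, Bayesian estimation by
    Metropolis-within-Gibbs sampling with data augmentation for missing weeks,
    per-person standardised cross-lagged effects averaged over participants,
    stratified contrasts, and a calibrated synthetic-data generator for the
    full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
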