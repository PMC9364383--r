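Package: coxsvb
Title: Sparse Variational Bayes for High-Dimensional Proportional Hazards Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scalable Bayesian variable selection and effect estimation for
    right-censored survival data with many covariates. Fits a proportional
    hazards model under a spike-and-slab prior (Dirac spike, Laplace slab)
    using a mean-field variational approximation optimized by coordinate
    ascent on the Cox partial likelihood. Provides posterior inclusion
    probabilities, posterior-mean coefficients, marginal credible sets,
    Bayesian false discovery rate selection, prognostic indices, pairwise
    risk-comparison probabilities, a Metropolis-within-Gibbs reference
    sampler for the exact posterior at small scale, a simulation harness
    for design-calibrated benchmarking, and cross-validation tuning of the
    prior hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    survival,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
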