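Package: seqtiming
Title: Sequential Bayesian Observer Models for Interval Timing Under Scalar Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits and simulates observer models of human time-interval
    reproduction when measurement and production noise scale with the timed
    duration (the scalar property). Implements the Bayes least-squares
    estimator for one and two measurements, a memory-augmented variant, a
    linear-nonlinear estimator, and an extended-Kalman-filter-style
    sequential updater; a lapse-augmented response model; quadrature-based
    trial likelihoods; cross-validated maximum-likelihood fitting with
    held-out model comparison; bias/variance/RMSE summaries with permutation
    tests; and a generator for complete synthetic sessions of the 1-2-Go /
    1-2-3-Go reproduction task including the adaptive correctness staircase.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    lhs,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
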