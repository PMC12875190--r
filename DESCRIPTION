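Package: rpalmrt
Title: Robust Paired-Permutation Tests for Covariate Effects in Linear Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finite-sample, distribution-free tests for the effect of a
    covariate of interest in a linear model adjusted for control covariates,
    built on a paired-permutation comparison of augmented model fits
    (RobustPALMRT).  Model fitting and model evaluation are decoupled:
    shipped fitters include ordinary least squares, Huber M-estimation with
    preliminary-regression MAD scale estimation, and quantile regression;
    shipped evaluation losses include L1, L2 and the scaled Huber norm.
    Includes DispersionPALMRT, a quantile-regression test for case/control
    differences in conditional inter-quantile range, confidence intervals by
    test inversion, classical baselines (partial F-test and the
    Koenker-studentized Breusch-Pagan test), and a seeded Monte-Carlo study
    harness with effect-size calibration for power comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    quantreg,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
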