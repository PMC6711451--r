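Package: peblm
Title: Parametric Empirical Bayes for Group Inference over Gaussian Posteriors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group-level (second-level) Bayesian inference over subject-level
    posterior parameter densities, as used in group effective-connectivity
    studies. Implements a two-level hierarchical Gaussian general linear model
    with design-matrix-encoded between-subject effects and additive random
    effects, estimated by variational free-energy maximisation with Newton
    ascent on log-precision hyperparameters. Hypotheses are tested by analytic
    Bayesian Model Reduction over factorial model spaces, family-wise pooling,
    Bayesian Model Averaging with posterior-probability thresholding, and a
    greedy search over reduced models. Predictive validity is assessed by
    leave-one-out cross-validation of between-subject covariates. Includes an
    exact conjugate linear first level for simulation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
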