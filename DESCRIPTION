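Package: longbart
Title: Longitudinal Soft Bayesian Additive Regression Trees and
    G-Computation for Mortal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Soft Bayesian additive regression tree (BART) samplers for
    Gaussian and probit outcomes with sparsity-inducing Dirichlet priors
    on split-variable selection, including a longitudinal grouped
    Dirichlet prior (LDART) that penalizes temporally distant predictors.
    Fits the sequential models of the G-formula for longitudinal cohorts
    with dropout and truncation by death, performs Monte-Carlo
    G-computation under the natural course and under an incremental
    threshold intervention on a continuous treatment, and computes two
    mortal-cohort estimands: the partly conditional intervention effect
    (PCIE) and the survivors average intervention effect (SAIE) with a
    stochastic-monotonicity sensitivity analysis. Includes a longitudinal
    Friedman-type simulation benchmark and a synthetic aging-cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
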