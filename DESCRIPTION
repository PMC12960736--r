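Package: coendorse
Title: Design-Based Analysis of Binary Co-Endorsement Surveys with Ising
    Network Estimation
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rare binary co-endorsement items from
    complex survey samples: post-stratification weighting by iterative
    proportional fitting (raking), design-based prevalence estimation with
    linearized variances, Rao-Scott second-order adjusted-F tests of
    independence, survey-weighted logistic odds ratios with sandwich
    standard errors, pairwise co-endorsement overlap and odds-ratio
    matrices, and conditional-dependence (Ising) network estimation by
    nodewise L1-penalised logistic regression with cross-validated
    one-standard-error penalty selection and AND-rule edge aggregation.
    Includes a synthetic cohort generator (exact-enumeration and Gibbs
    samplers for binary Markov random fields, demographic covariate
    effects, and biased sampling) so that every stage of the pipeline is
    verifiable by oracle equivalence and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
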