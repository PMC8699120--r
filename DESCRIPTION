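Package: oxalipk
Title: Population Pharmacokinetics of Intact Oxaliplatin in Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for population pharmacokinetic
    studies of intact oxaliplatin in rats with acute kidney injury. Provides
    the closed-form two-compartment intravenous-bolus model, a synthetic study
    generator matching the rat ischemia-reperfusion study design (three renal
    groups, two dose levels, dense early sampling, urine collection),
    non-compartmental analysis, a first-order conditional estimation with
    extended least squares (FOCE-ELS) nonlinear mixed-effects estimator with
    empirical Bayes estimates and conditional weighted residuals, model
    qualification by nonparametric bootstrap and prediction-corrected visual
    predictive check, and Monte Carlo simulation of drug exposure as a
    function of plasma creatinine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
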