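Package: orinpk
Title: Population Pharmacokinetics of Oral ORIN1001
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Nonlinear mixed-effects analysis of oral ORIN1001, a
    first-in-class IRE1-alpha RNase inhibitor in clinical development for
    advanced solid tumors. Implements a two-compartment disposition model
    with lagged first-order absorption in closed form, a hierarchical
    population layer with power-of-median covariate effects, FOCE
    (first-order conditional estimation with interaction) likelihood
    approximation and fitting, stepwise covariate selection with Pearson
    collinearity pre-screening, model diagnostics (goodness-of-fit,
    non-parametric bootstrap, visual predictive checks, normalized
    prediction distribution errors), non-compartmental analysis with a
    dose-proportionality assessment, steady-state exposure simulation for
    covariate effect evaluation against the 80-125 percent window, and a
    synthetic-trial generator emulating the phase I sparse-sampling design
    so the whole pipeline is testable without confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
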