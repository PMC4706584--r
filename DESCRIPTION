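Package: trastupk
Title: Population Pharmacokinetics and Exposure-Response for Subcutaneous and
    Intravenous Trastuzumab
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of trastuzumab given
    as a fixed 600 mg subcutaneous dose or as weight-based intravenous
    infusions. Implements a two-compartment structural model with parallel
    linear and Michaelis-Menten (target-mediated) elimination and first-order
    subcutaneous absorption; power/exponential covariate models on clearance
    and distribution volumes; regimen simulation with steady-state exposure
    metrics; a first-order conditional (FOCE-with-interaction)
    marginal-likelihood estimation engine with two-step covariate selection,
    nonparametric bootstrap and shrinkage diagnostics; weighted-residual
    outlier screening and visual/numerical predictive checks; multiple
    logistic regression linking exposure to pathologic complete response and
    grade >=3 adverse events; and a synthetic-trial generator emulating the
    phase III subcutaneous-versus-intravenous study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
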