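Package: venpk
Title: Joint Population Pharmacokinetics of Venlafaxine and
    O-Desmethylvenlafaxine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for joint population-pharmacokinetic analysis of
    venlafaxine (VEN) and its active metabolite O-desmethylvenlafaxine
    (ODV).  Implements a one-compartment parent-metabolite structural
    model with depot absorption and pre-systemic (first-pass) conversion,
    closed-form single-dose, multiple-dose and steady-state predictions
    with an ODE cross-check, first-order conditional estimation with
    interaction (FOCEI) for log-normal between-subject variability and
    proportional residual error, stepwise covariate modeling by
    likelihood-ratio thresholds, conditional weighted residual and
    normalized prediction distribution error diagnostics, and generators
    for synthetic bioequivalence-style and therapeutic-drug-monitoring
    datasets in a NONMEM-dialect CSV format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
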