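Package: pkdual
Title: Population Pharmacokinetics of Oral Drugs with Dual First-Order Absorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population pharmacokinetic analysis of single oral
    doses whose plasma profiles show a double peak, modelled as a
    two-compartment disposition with two parallel first-order absorption
    paths, the second delayed by a lag time. Provides the analytic
    concentration solution with an ODE cross-check, non-compartmental
    analysis with group comparison, maximum-likelihood estimation of the
    hierarchical (nonlinear mixed-effects) model by stochastic approximation
    EM with formulation covariates and proportional residual error,
    model diagnostics (individual predictions, shrinkage, visual predictive
    checks, normalized prediction distribution errors, nonparametric
    bootstrap), external predictive-performance metrics, and a virtual
    dog-study simulator for design evaluation and method testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    deSolve,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
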