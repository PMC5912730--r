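Package: mousetci
Title: Brain Target-Controlled Infusion of Propofol in Mice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Three-compartment pharmacokinetic modelling of propofol
    distribution between blood, brain and peripheral tissue in mice,
    with exact linear-time-invariant propagation of piecewise-constant
    infusions, constrained multi-start estimation of the rate constants
    from timed blood and brain concentration samples, a STANPUMP-style
    target-controlled-infusion (TCI) planner that holds brain
    concentration at a chosen level by impulse-response convolution,
    infusion-performance diagnostics (MDPE/MDAPE, drift slope,
    Ljung-Box residual autocorrelation, rank-sum window comparison,
    normalized moving statistics), and a seeded synthetic-experiment
    generator so every stage is testable without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
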