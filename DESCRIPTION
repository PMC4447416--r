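Package: causalmap
Title: Causal Mapping of Biological Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, validate and simulate causal-map (CMAP) models of
    signaling pathways: signed multi-order influence networks advanced by a
    discrete-time bounded sigmoidal update rule. Includes a one-to-one
    translator from mass-action ordinary-differential-equation models
    (with optional Hill saturation terms) into influence graphs, a
    rule-based random parameter-ensemble search (increase, decrease,
    transient and oscillation criteria), a fixed-step Runge-Kutta
    reference integrator for the source ODE models, and a packaged
    insulin-signaling case study comparing normal and type-2-diabetes
    conditions, with a command-line interface over all of it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
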