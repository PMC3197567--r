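Package: cdtarget
Title: Tissue Targeting of Chemicals via Complex Degradation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the targeting of a biologically active chemical to a tissue
    by delivering it as a complex with a binding partner that is degraded within
    the tissue. Implements the coupled three-species reaction-diffusion system
    (free chemical, binding partner, complex) on a symmetric one-dimensional
    domain: closed-form leading-order steady-state solutions in the
    small-complex-formation-rate regime, the first-order perturbation
    corrections with an independent boundary-value-problem oracle, a
    semi-implicit (IMEX) finite-difference solver for the full nonlinear
    system run to steady state, parameter-sweep experiment drivers with
    regime classification of the steady profiles, and JSON/CSV configuration
    and output utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
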