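Package: ppsim
Title: Agent-Based Simulation of Peyer's Patch Organogenesis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic agent-based model of murine Peyer's patch (PP)
    formation in the embryonic gut over the E14.5-E17.5 developmental window.
    Lymphoid tissue initiator (LTin) cells perform an unbiased random walk and
    trigger differentiation of stationary stromal organiser (LTo) cells on
    contact; inducer (LTi) cells are attracted by chemokine expressed from
    differentiated LTo cells and arrest near them, producing emergent cell
    aggregations (immature patches). The package ships the calibrated baseline,
    cumulative cell-input schedules (linear, exponential, square-root) anchored
    to the E15.5 cell-count estimate, spatial patch detection, the
    Vargha-Delaney A-Test with effect-magnitude classification, a
    replicate-consistency analysis, and drivers for the two assumption
    experiments: perturbation of the E15.5 LTin cell count and replacement of
    the LTin migration-rate function.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
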