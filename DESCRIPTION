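Package: macropin
Title: Phase-Field Simulation of Macropinocytic Cup Formation and Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the self-organized formation and closure of macropinocytic
    cups by coupling a phase-field description of the deformable plasma membrane
    to a mass-conserved, bistable/excitable reaction-diffusion system of an
    active signalling patch confined to the membrane. Provides a quasi-3D
    axisymmetric explicit finite-difference solver with cup-closure detection
    and enclosed-volume estimation, a full 3-D Cartesian solver with solid-bead
    engulfment and stochastic patch nucleation, well-mixed (space-free) analysis
    of the patch kinetics (fixed points, linear stability, patch-annihilation
    condition), a reduced patch-boundary model, phase-diagram sweeps, and
    plain-text configuration, snapshot, and run-manifest I/O.
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
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
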