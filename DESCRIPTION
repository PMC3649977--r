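Package: apopSTL
Title: Signal Temporal Logic Analysis of ODE Models of Extrinsic Apoptosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative (robustness) monitoring of signal temporal logic (STL)
    properties on simulated trajectories of mass-action reaction networks, with an
    application to TRAIL-induced extrinsic apoptosis. Bundles a transcription of the
    EARM1.4 extrinsic apoptosis reaction model with cell-line-specific initial
    concentrations, the three type I/II distinguishing properties (clonogenic survival
    under Bcl2 over-expression, sequential caspase activation, MOMP-gated death),
    STL and direct finite-time Lyapunov exponent (DLE) phase diagrams over
    initial-concentration slices, lognormal cell-population statistics, and an
    STL-guided two-phase parameter search against an observed property truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, deSolve, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
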