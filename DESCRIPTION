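Package: pepTurnover
Title: Peptide-Level Turnover Kinetics from Pulsed SILAC Time Courses
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kinetic modelling and statistical analysis of peptide-level
    pulsed-SILAC turnover data. Defines first-order
    synthesis-modification-degradation compartment models of proteoform
    interconversion, computes steady states and old-pool clearance profiles
    for arbitrary peptide observables, and provides the full data pipeline:
    growth correction of SILAC ratios using replicate-specific cell-cycle
    times, a calibrated spline F-test that detects peptides whose clearance
    deviates from their protein reference, faster/slower classification by
    initial slope, and nonlinear fitting of the simplified two-species model
    to recover modification writing and erasing rate constants, site
    occupancy, and mean time to modify. A bundled synthetic pulsed-SILAC
    generator with known ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    splines,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
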