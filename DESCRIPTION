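Package: erqc
Title: Kinetic Modeling of Glycoprotein Quality Control in the Endoplasmic Reticulum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-action model of the chaperone-mediated glycoprotein
    quality-control cycle in the endoplasmic reticulum. Provides the
    dimensionless cycle dynamics, an analytic steady-state solution via a
    quartic equation in the available chaperone concentration, performance
    metrics (folding fraction, total unfolded protein, cycle driving energy),
    seven pathway-architecture variants, constrained optimization of folding
    efficiency (Pareto frontiers, energy-constrained optima, degradation-rate
    adaptation), reproducible parameter-sweep drivers, and a scenario-file
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
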