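Package: racemizr
Title: Predicting Aqueous Racemization Kinetics of Stereogenic Carbon Centers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies carbon stereogenic centers bearing a single
    alpha-hydrogen, classifies their substituents, and scores the risk of
    general-base-catalyzed racemization under physiological conditions. A
    group-contribution model sums per-substituent carbanion-stabilization
    energies (with a cross-conjugation correction) and calibrated linear
    free-energy relationships map the score to second-order racemization
    rate constants, half-lives and fraction racemized in a blood-equivalent
    phosphate buffer. Also provides the kinetic-analysis chain that derives
    such rate constants from experimental decay traces: pseudo-first-order
    exponential fits, buffer-dilution plots, hydrolysis, protonation-state
    and temperature corrections, and Hammett sigma/sigma-minus comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
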