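Package: phostat
Title: Transport-Centric Modeling of the Yeast Pho Regulon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how membrane transporter biophysics can
    govern inorganic phosphate homeostasis and the phosphate starvation
    response of Saccharomyces cerevisiae. Implements the steady-state flux
    law of a symmetric alternating-access carrier together with a
    Michaelis-Menten comparator, inverts either flux law at a constant
    consumption demand to obtain internal-versus-external concentration
    curves, critical starvation thresholds and robustness indices, and
    simulates a dual-transporter Pho regulon state machine (low-affinity
    constitutive carriers inactivated by Spl2, Pho4-induced high-affinity
    carriers, a three-level Pho4 nuclear transfer function and two promoter
    activation classes) that reproduces the off/plateau/on expression
    program with bistability and hysteresis. Also provides a histogram
    based nuclear-localization score for fluorescence images, an
    activated-cell trace statistic, and seeded generators of synthetic
    microscopy images and single-cell reporter populations so that every
    analysis stage can be validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    deSolve,
    withr,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
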