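Package: runwheel
Title: Home-Cage Running-Wheel Phenotyping for Mouse Models of Motor Decline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of voluntary home-cage running-wheel
    activity in mice, aimed at early, low-burden detection of motor
    dysfunction in SOD1-G93A-like disease models. Provides a calibrated
    generator of wheel-rotation event streams over a disease course,
    reduction of event streams to the four daily odometer metrics (distance,
    running time under a 5-second inter-rotation gap rule, average and
    maximum speed) with censoring support, per-animal detection of the age
    at first sustained 20 percent decline from a rolling-peak baseline,
    cohort reproducibility summaries (within- and between-study coefficients
    of variation), onset survival curves with log-rank and rank-based group
    comparisons, and exact noncentral-t power and minimum group-size
    calculations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
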