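Package: ovifnirs
Title: Multi-Distance fNIRS Analysis for Freely Moving Sheep
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous-wave functional near-infrared
    spectroscopy (fNIRS) recordings from freely moving sheep measured with
    short (10 mm) and long (30 mm) source-detector channels at 751 and 839 nm.
    Implements closed-form and semi-analytic photon-diffusion forward models
    (CW homogeneous semi-infinite, CW two-layer, time-resolved homogeneous),
    differential pathlength factor computation, a seeded Monte Carlo photon
    transport oracle for layered media, the two-step inversion of short- and
    long-distance optical-density changes into extra-cerebral and cerebral
    absorption changes, Beer's-law conversion to oxy- and deoxy-hemoglobin,
    ethogram-driven block exclusion with Move/Stand stratification, group
    averaging and activation statistics, and a ground-truthed synthetic-data
    generator so that every stage is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
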