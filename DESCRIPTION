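Package: shoalkit
Title: Collective-Motion Analysis for Small Fish Shoals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing the collective motion of small groups of
    individually tracked fish. Reads idTracker-style and tabular trajectory
    exports, computes per-individual kinematics (velocity, speed, unit
    headings), group polarization, nearest-neighbour distances and median
    speeds per sampling period, pairwise directional-correlation surfaces
    binned by mutual speed and distance, and focal-frame alignment maps.
    Fits the matching repeated-measures mixed models (between-subjects
    familiarity, within-subjects sampling period, individuals nested in
    groups) with Benjamini-Hochberg false-discovery-rate control, and ships
    an agent-based shoal simulator for annular arenas so that the whole
    pipeline can be exercised and calibrated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nlme,
    car,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
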