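Package: boneCSG
Title: Cross-Sectional Geometry of Long-Bone Diaphyses from Surface Meshes
Version: 0.1.0
Authors@R: person("boneCSG", "Developers", role = c("aut", "cre"),
    email = "bonecsg@example.org")
Description: Automated cross-sectional geometry analysis of femur-like long
    bones from watertight triangle meshes. Loads, cleans, decimates and
    orients STL surface models, extracts evenly spaced diaphyseal
    cross-sections between 20 and 80 percent of biomechanical length,
    classifies periosteal and endosteal contours, places equiangular
    semilandmarks from the medullary centroid, and computes beam-theory
    section properties (areas, perimeters, cortical thickness, second
    moments of area, principal moments, section moduli, polar quantities).
    Includes a parametric synthetic-bone generator with closed-form ground
    truth and an osteoporosis mode, cohort-level group statistics, and a
    command-line pipeline for simulate/process/compare runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
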