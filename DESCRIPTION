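Package: vpcalcium
Title: Single-Cell Calcium Imaging and Spatial Analyses of Ventral
    Pallidum Neuron Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for one-photon miniscope calcium imaging of
    ventral pallidum (VP) neuron subtypes during cocaine self-administration,
    extinction, and cue-induced reinstatement. Covers movie preprocessing
    (spatial downsampling, rigid motion correction, dF/F normalization),
    PCA/ICA cellular source extraction, Ca2+ transient event detection and
    session-level event statistics, peri-event z-score analysis with
    responder classification, a k-nearest-neighbor spatial clustering
    permutation test, colocalization and rabies input-fraction counting, and
    the inferential statistics used with these analyses (paired and
    one-sample t tests, repeated-measures ANOVA with Greenhouse-Geisser
    correction, Student-Newman-Keuls post hoc tests, chi-square with
    Bonferroni adjustment). Includes seed-deterministic synthetic-data
    generators with exported ground truth for every stage.
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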