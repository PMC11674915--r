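Package: amdnet
Title: Lightweight Inception/SE/ConvMixer Network for Retinal OCT Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Declarative construction, parameter auditing, training and
    evaluation of a compact convolutional network for classifying retinal
    OCT B-scans into age-related macular degeneration (AMD) categories.
    The architecture combines a depthwise-separable stem, a modified
    Inception module, a depthwise squeeze-and-excitation block and a
    ConvMixer stage. The package provides analytic per-layer parameter
    accounting, an executable model with a pure-R/Rcpp training engine
    (Adam, plateau learning-rate decay, best-checkpoint retention),
    macro-averaged multiclass evaluation metrics, deterministic 70/15/15
    dataset partitioning, and a seeded synthetic OCT B-scan generator for
    desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
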