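Package: balloonbrachy
Title: Monte Carlo Backscatter Dosimetry for Multilumen Balloon
    Brachytherapy Applicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying missing-backscatter
    underdose in accelerated partial breast irradiation with a multilumen
    balloon applicator and an Ir-192 high-dose-rate source. Provides an analog
    photon Monte Carlo transport engine with track-length and collision kerma
    estimators, a homogeneous-water single-dwell dose kernel acting as a
    TG-43-style treatment-planning surrogate, symmetric and maximally
    asymmetric dwell-weight plans with V150/V200 evaluation against RTOG 0413
    limits, dose modification factor (DMF) curves over tissue depth in cuboid
    and spherical water phantoms, steel source-wire sensitivity studies with
    common random numbers, and a deterministic scenario generator for the full
    study matrix.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
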