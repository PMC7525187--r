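Package: cardioflow
Title: Optical-Flow Contractility and Field-Potential Analysis for
    Beating Cardiomyocyte Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Video-based contractility analysis for beating cardiomyocyte
    monolayers and a matching multielectrode-array (MEA) metric layer.
    Displacement fields between a resting reference frame and every other
    frame are estimated by two-stage tile-based cross-correlation block
    matching (64-pixel coarse tiles, thin-plate-spline smoothing, 32-pixel
    refinement within a four-pixel search), reduced to a beat pattern D(t),
    and characterized by discrete-Fourier power spectra and convergence
    (negative-divergence) maps that localize contractile centers. Field
    potential traces yield beat period, field potential duration (FPD),
    Fridericia-corrected FPD, spike amplitude, and a beat-period
    irregularity flag. A synthetic-scene module generates textured
    monolayer videos deformed by known contraction fields and MEA-like
    traces with known spike times, so every stage is testable against
    analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
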