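Package: cortexmap
Title: Simulation and Analysis of Cortical Orientation and Ocular Dominance Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling and analysing the joint layout of orientation
    preference (OP) and ocular dominance (OD) maps in primary visual cortex.
    Includes an annealed elastic-net simulator of joint OP/OD map development
    with per-feature coverage weighting to model biased (cross-reared) visual
    input; map statistics (pinwheel detection by winding number, pinwheel
    density relative to the Fourier map wavelength, ocular-dominance quintile
    localisation of pinwheels, orientation-proportion histograms with fixed
    period sine fits, and OP/OD contour crossing angles); recovery of feature
    maps from intrinsic-signal optical imaging stacks by single-shift extended
    spatial decorrelation (ESD); single-unit tuning-curve models (von Mises
    orientation tuning, skewed log-Gaussian frequency tuning, Naka-Rushton
    contrast response, monocularity index); and seed-deterministic synthetic
    generators for ground-truth maps, imaging stacks and unit responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
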