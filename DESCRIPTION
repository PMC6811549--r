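Package: spinephys
Title: Dendritic Spine Function and Integration Analysis for Patch-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sweep-level feature extraction and group-level statistics for
    whole-cell patch-clamp studies of layer-4 stellate cell dendritic spine
    function: uncaging-evoked EPSC/EPSP quantification with silent-spine
    classification, moving-template miniature EPSC detection, passive and
    active intrinsic properties (input resistance, rheobase, F-I, sag and
    rebound, chirp impedance resonance), voltage-clamp isolation of the
    hyperpolarization-activated current with Boltzmann activation fits,
    multi-spine summation linearity analysis, and a nested (litter/animal/
    slice) mixed-model comparison layer. Includes a conductance-based
    point-neuron simulator with genotype presets that generates complete
    synthetic cohorts with known ground truth for every protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
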