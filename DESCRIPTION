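Package: meridianvis
Title: Meridian-Specific Spatial Vision from Contrast Sensitivity
    Staircases and Sweep Visual Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying meridian-specific spatial vision with
    two complementary measurement chains: (1) psychophysical contrast
    sensitivity functions (CSF) estimated from three-down one-up
    adaptive staircases on a two-interval forced-choice grating
    detection task, summarised as the area under the log CSF (AULCSF),
    CSF acuity and the spatial-frequency threshold at 80% contrast; and
    (2) sweep visual evoked potentials (sVEP), analysed by zero-phase
    band-pass filtering, epoching, recursive-least-squares harmonic
    extraction at the second harmonic, coherent (vector) trial
    averaging, signal-to-noise gating and regression-to-zero-amplitude
    threshold estimation. A synthetic observer and EEG generator with a
    configurable strong/weak meridian asymmetry makes every stage
    testable without human data, and a statistics layer produces
    meridional-disparity reports with paired and two-sample contrasts,
    Bonferroni adjustment and cross-paradigm correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
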