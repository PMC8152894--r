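Package: ramplab
Title: Corticostriatal Ensemble Analysis for Fixed-Interval Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-unit recordings from medial frontal
    cortex and dorsomedial striatum during fixed-interval timing tasks with one
    or two intervals (3 s and 12 s). Quantifies time-related ramping by ensemble
    principal component analysis of kernel-density peri-event time histograms,
    decodes time within the interval from ensemble firing rates with a naive
    Bayes classifier under leave-one-out cross-validation and a time-shuffled
    null, estimates single-trial behavioral start times and their coefficient of
    variation, classifies striatal units by waveform shape, screens units for
    interval-dependent firing, and fits the associated mixed-effects models.
    Includes an inhomogeneous-Poisson spike and behavior simulator with ground
    truth so every stage is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
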