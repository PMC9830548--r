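Package: swdscore
Title: Sleep Staging and Spike-Wave Discharge Detection for Mouse
    EEG/EMG Polysomnography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end quantification pipeline for rodent
    polysomnography in genetic epilepsy studies. Scores wake/NREM/REM
    vigilance states on a 10-second epoch grid with a >5 s dominance
    rule, detects spike-wave discharges (6-12 Hz), slow spike-wave
    discharges (3-6 Hz) and sleep spindles (10-15 Hz) with
    state-dependent amplitude criteria, estimates NREM delta power by
    multitaper spectral analysis, and summarises per-animal incidence
    metrics with group statistics (t-tests, one-way ANOVA, Holm-Sidak).
    Includes EDF and delimited-text I/O and a ground-truthed synthetic
    polysomnography generator so every stage is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
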