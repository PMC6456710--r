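Package: tvarnet
Title: Time-Varying Directed EEG Networks via the Adaptive Directed Transfer Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-locked time-varying effective-connectivity analysis for
    multichannel EEG. Fits a time-varying multivariate adaptive autoregressive
    (TV-MVAAR) model with a multi-trial Kalman-filter tracker, derives the
    adaptive directed transfer function (ADTF), band-integrated directed
    couplings and the normalized total information outflow of each node,
    and characterizes network dynamics: surrogate-calibrated edge thresholds,
    key-node (hub) trajectories and their conversion times, enhanced and
    weakened edge intervals relative to a pre-event baseline, scalp-region
    aggregation and modularity-based module partitioning. Includes a fully
    ground-truthed synthetic-data module (piecewise nonstationary MVAR
    simulator, TMS-pulse event trains, attention-task digit streams and
    behavioral logs) used to validate every stage, readers and writers for
    EDF, BrainVision and a plain fixture format, and an end-to-end pipeline
    driver with tidy outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    signal,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
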