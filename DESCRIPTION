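Package: dfnc
Title: Dynamic Functional Network Connectivity States and Meta-States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for static and dynamic functional network connectivity
    (FNC) analysis of network component time courses from resting-state
    fMRI. Implements time-course conditioning (detrending, despiking,
    zero-phase Butterworth low-pass filtering), tapered sliding-window
    correlation with optional graphical-LASSO-regularised precision
    estimation, k-means clustering of windowed connectivity under the L1
    distance with elbow-based model selection, state occupancy metrics
    (mean dwell time, fraction time, number of transitions), meta-state
    decomposition into maximally independent connectivity patterns with
    signed quartile discretisation and four dynamism indices, and
    FDR-corrected correlation of connectivity features with behavioural
    measures. Includes a synthetic-cohort generator with Markov-switching
    covariance states and planted behavioural effects so that every stage
    of the pipeline can be exercised and validated without access to
    scanner data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
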