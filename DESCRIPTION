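Package: calico
Title: Calcium Imaging Transient Analysis and Population Co-Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-photon calcium imaging of
    hippocampal pyramidal neuron populations: sliding-percentile baseline
    estimation and delta-F/F computation, Savitzky-Golay smoothing, calcium
    transient detection and small/large event classification, juxtacellular
    ground-truth calibration of spikes to fluorescence (calibration curves,
    interspike-interval clustering, a model-free mean-dF/F to action-potential
    look-up table with a Gaussian-process confidence corridor), nonnegative
    kernel deconvolution to instantaneous spike rates, behavioral-state
    resolved event statistics, and longitudinal population statistics
    (pairwise co-activity with shuffle nulls, across-day stability, and
    Monte Carlo large-event incidence nulls). A first-class synthetic-data
    generator emulates bursty spike trains, a calibrated spike-to-fluorescence
    forward model, locomotion-dependent large events, and multi-day sessions
    with planted co-activity, so every stage can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
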