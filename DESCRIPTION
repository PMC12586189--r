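Package: resphrv
Title: Respiratory Heart Rate Variability from Cardiorespiratory Recordings
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies respiratory sinus arrhythmia (respiratory heart rate
    variability, RespHRV) from multichannel cardiorespiratory recordings of
    rodents: R-peak and systolic-peak detection, whole-body plethysmography
    breath segmentation, nerve-burst detection, respiratory-triggered averaging
    of heart rate aligned to end-inspiration, per-epoch metrics (mean heart
    rate, RespHRV amplitude, respiratory frequency and amplitude), respiratory
    modulation of integrated nerve activity, inhibitory synaptic-drive
    envelopes, and pre/post effect statistics with stress-recovery kinetics.
    Includes an integral-pulse-frequency-modulation (IPFM) generator of
    synthetic cardiorespiratory sessions with known ground truth for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
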