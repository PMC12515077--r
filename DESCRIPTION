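Package: alphabold
Title: EEG-Informed fMRI Analysis of Sensorimotor Alpha-BOLD Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for EEG-informed fMRI analysis of motor execution and motor
    imagery. Builds continuous sensorimotor alpha-power regressors from C3/C4
    EEG (Morlet time-frequency analysis, event-related desynchronization,
    condition masking, canonical HRF convolution, TR resampling, 128 s
    high-pass), fits mass-univariate GLMs with lateralized t-contrasts,
    thresholds and clusters statistical maps, and validates EEG-informed maps
    against conventional block-design fMRI maps with Dice, precision and
    recall. Includes a synthetic EEG+BOLD generator with planted neurovascular
    coupling so the whole pipeline is testable without real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    rlang,
    RNifti,
    readr,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
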