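Package: fatiguebrake
Title: EEG Spectral Fatigue Scoring and Ship Emergency Braking Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline linking driver fatigue, measured from
    electroencephalography (EEG), to ship emergency-braking safety. Extracts
    centroid frequency and power spectral entropy from multi-channel EEG,
    correlates them with subjective fatigue ratings on the five-point Fatigue
    Severity Scale, fits an analytic ridge-regression fatigue score with
    k-fold cross-validation, and propagates the predicted fatigue level into a
    three-stroke (reaction, reversing, braking) ship stopping-distance model.
    Includes a synthetic EEG and Stroop-task cohort generator calibrated to
    the packaged study tables, so the full pipeline runs and is testable
    without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
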