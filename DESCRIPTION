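Package: alphagate
Title: Alpha-Band Gating Indexes and Robust Neural-Behavioral Correlation for
    Stroke Rehabilitation EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Response-locked alpha-band (8-12 Hz) EEG analysis for stroke
    rehabilitation studies built around the gating-by-inhibition model:
    Morlet-wavelet power with participant-level median-scaled dB transform,
    cluster-based permutation selection of analysis windows, temporal and
    central-frontal regional alpha indexes and their ratio, skipped robust
    correlations (exhaustive minimum-covariance-determinant outlier rejection,
    box-plot rule, percentile-bootstrap confidence intervals) between index
    changes and clinical activities-of-daily-living change scores, and the
    group-by-time mixed ANOVA screening stage. A synthetic-data module
    generates multichannel EEG cohorts and clinical score tables with planted
    effects so the whole pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    withr,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
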