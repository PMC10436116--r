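Package: wearwalk
Title: Daily Walking Measures from Wearable Step-Count Epochs with
    Accuracy and Time-to-Reliability Characterization
Version: 0.1.0
Authors@R:
    person("Wearwalk", "Maintainers", email = "maintainers@wearwalk.org",
           role = c("aut", "cre"))
Description: Computes a suite of daily walking measures (step count,
    walking-bout counts and durations, peak 30-minute cadence and pace,
    ambulatory and wear time) from 10-second-epoch step counts recorded by
    body-worn devices.  Provides two characterization analyses for such
    digital measures: between-device agreement (Fisher intraclass
    correlation, Pearson correlation, mean error, mean absolute error,
    Bland-Altman limits of agreement, with participant-clustered bootstrap
    confidence intervals) and a time-to-reliability procedure that computes
    test-retest ICCs between adjacent non-overlapping windows across
    aggregation scopes of 1-30 days.  Includes a synthetic cohort generator
    with controllable between- and within-subject variance components,
    bout-structured walking, wear patterns, and two-device measurement
    noise, so the full pipeline is testable without access to raw study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
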