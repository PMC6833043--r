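Package: mobagree
Title: Agreement Between GPS-Derived and Self-Reported Daily Mobility
    Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts daily mobility indicators - time out of home and
    number of activity locations - from raw GPS fix streams and paper
    travel diaries, and quantifies their agreement. Provides speed-based
    outlier filtering, day segmentation with validity flagging,
    density-based home-location validation, geofence extraction of
    out-of-home events with temporal gap interpolation, time-based stop
    detection with noise merging, diary validation with exclusion
    logging, event-level (precision, recall, F1, interval
    intersection-over-union, match cardinalities) and day-level
    (repeated-measures Bland-Altman, intraclass correlation, Spearman and
    within-person correlations) agreement statistics, stepwise threshold
    sensitivity analysis, and a synthetic cohort simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    xml2,
    yaml,
    withr,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
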