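Package: dqspc
Title: Data Quality Scoring and Statistical Process Control for Clinical
    Encounter Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based scoring of clinical encounter records on three data
    quality dimensions (same-day entry timeliness, completeness, and date
    validity), aggregation of the resulting flags into percentage measure
    series by user and by calendar month, XmR (individuals and moving-range)
    control charts with assignable-cause signal detection, and paired
    pre-post intervention analysis (paired t test, Cohen's d on paired
    differences, and normal-approximation power). Includes a calibrated
    synthetic encounter-cohort generator emulating per-user entry-delay
    behaviour, an unknown-referral-date sentinel, rare validity errors,
    quarter-end seasonality, and a step-change intervention, so the whole
    pipeline is testable without access to organisational data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    patchwork,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    lubridate,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
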