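Package: usvscore
Title: Occupancy-Normalized Scoring of Rat Ultrasonic Vocalizations in
    Social-Sucrose Preference Maze Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synchronizes manually annotated rat ultrasonic-vocalization
    (USV) labels with video position tracking on a 25 Hz frame raster,
    assigns maze zones to frames, and computes occupancy-normalized
    vocalization scores (combined and per 50-kHz subtype), behavioral
    preference scores, and subtype prevalence filters for X-maze sucrose
    discrimination and social-sucrose preference sessions. Includes the
    within-subject statistical battery (repeated-measures ANOVA with
    Bonferroni post hocs, rank tests with exact small-sample nulls,
    random-intercept mixed linear models, Cohen's kappa) and a synthetic
    session generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    readr,
    tibble,
    yaml,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    dplyr
Config/testthat/edition: 3
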