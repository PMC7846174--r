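Package: circatime
Title: Circadian Physiological Time Inference from Static Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a modified molecular-timetable method for inferring
    the physiological circadian time of a single static transcriptome from a
    reference time series: cosine-bundle rhythmicity scoring, selection of
    time-indicating genes by correlation and coefficient-of-variation
    filters, molecular peak-time assignment, and single-sample phase
    prediction.  Ships a leave-one-out evaluation harness with 3-SD precision
    calibration and outlier flagging, a detection-window simulation for lines
    with deviating molecular periods or phases, cosinor rhythmometry with a
    between-group phase-shift test, and a synthetic circadian expression
    generator emulating two-day reference designs and high-frequency static
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
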