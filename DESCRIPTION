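Package: knapgaze
Title: Perceptuomotor Gaze Analysis for Observational Learning of Stone Toolmaking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing eye-tracking data collected
    while novices repeatedly watch an expert stone knapper at work. Button-press
    logs are converted into a subject-by-time salience matrix from which
    high-probability "core move" analysis windows are selected; gaze dispersion
    inside those windows is quantified by the coefficient of variation and by
    Ward agglomerative clustering of the time-by-subject gaze matrix; the core's
    working edge is tracked across video frames with a RANSAC point-cloud
    registration so gaze can be referenced to it; session-to-session change is
    summarised with Harrell-Davis decile shift functions (percentile bootstrap,
    Hochberg correction) and effect sizes; and gaze and motor-performance
    variates are linked by a whitening-plus-SVD canonical correlation analysis.
    A fully seeded synthetic-experiment generator with planted ground truth
    makes every stage testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
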