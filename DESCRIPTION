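Package: sacmod
Title: Saccadic Latency Modulation Analysis for Video-Oculography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of saccadic latency (SL) modulation by
    cognitive task demand. Provides a synthetic video-oculography cohort
    generator with main-sequence saccade kinematics, a velocity-threshold
    saccade detector (60/15 deg/s onset/offset thresholds on an
    artifact-masked, 20 ms moving-average smoothed velocity signal),
    per-trial saccadic latency extraction with validity QC, the group
    statistics of a two-task (color vs Landolt) latency-modulation design
    (paired and Welch t-tests, RMS-pooled Cohen's d, saccadic latency
    difference, Levene and rank tests, mixed-design ANOVA, noncentral-t
    power for paired designs), and Monte Carlo balanced-subsample SVM
    classification with leave-one-out cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    car,
    jsonlite
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
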