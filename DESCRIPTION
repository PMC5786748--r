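Package: liftpost
Title: Posturography of Self-Triggered Weight Lifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for centre-of-pressure (COP) responses to
    self-triggered lifting of a small barbell on a piezoelectric force
    platform. Converts four vertical force-sensor channels into COP
    stabilograms, calibrates a one-axis barbell accelerometer to lift angle,
    detects lift onsets from the acceleration derivative, segments trials
    around movement onset, forms group grand averages with pointwise
    confidence bands, and computes anticipatory and compensatory postural
    metrics (pre-onset window means, forward-peak amplitude and latency,
    return-to-baseline offsets, lateral compensation indices, oscillation
    frequency) together with split-plot repeated-measures ANOVA with
    Mauchly/Greenhouse-Geisser handling. Includes a synthetic-cohort
    generator that emulates the postural signatures of healthy controls,
    idiopathic Parkinson's disease and progressive supranuclear palsy, with
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
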