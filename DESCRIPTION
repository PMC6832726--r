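Package: gaitquality
Title: Daily-Life Gait Quality, Variance Components, and Trial Sample Size
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes gait-quality characteristics (regularity, intensity,
    symmetry, smoothness, stability, complexity) from trunk-worn tri-axial
    accelerometer locomotion episodes, aggregates them to weekly medians per
    subject, estimates between-subject, within-subject and error variance
    components across two measurement weeks by repeated-measures ANOVA, and
    computes the number of participants required to detect a standardized
    intervention effect in a paired pre/post design. Includes seeded
    synthetic generators for gait-like acceleration signals and for
    feature-level cohorts following the additive variance-component model,
    so every stage of the pipeline can be exercised against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
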