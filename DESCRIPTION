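Package: velift
Title: Predicting Running Velocity in the 30-15 Intermittent Fitness Test
    from Accelerometry and Heart Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to predict instantaneous running velocity during the
    30-15 Intermittent Fitness Test from tri-axial accelerometry-derived
    load metrics (Player Load, Average Net Force) and heart rate.
    Implements the test's stage protocol, a protocol-faithful synthetic
    cohort generator (100 Hz accelerometer and 1 Hz heart-rate traces),
    envelope-based artifact masking, 30-s run-window segmentation with
    trimmed-mean heart rate, the load-metric formulas, z-scored
    linear-kernel support-vector regression under leave-one-subject-out
    cross-validation with univariate baselines, and the evaluation
    battery: Pearson correlation with qualitative magnitude bands,
    predicted-versus-actual linear fits, Bland-Altman limits of
    agreement, paired t-tests, Fisher r-to-z model comparisons, and
    descriptive statistics with coefficients of variation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
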