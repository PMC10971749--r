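Package: depscreen
Title: EEG-Based Depression Screening from Temporal-Domain Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening major depressive disorder
    from short resting-state electroencephalography (EEG) recordings made
    with a three-electrode pre-frontal montage (Fp1, Fpz, Fp2). Provides
    readers for European Data Format (EDF) and delimited recordings,
    signal cleaning (average reference, zero-phase 50 Hz notch, moving-average
    smoothing), non-overlapping windowing, a bank of twelve temporal-domain
    statistics per channel, correlation-based feature-subset selection run
    per electrode and fused by a majority rule, from-scratch k-nearest-neighbour,
    AdaBoost and best-first decision-tree classifiers, stratified and nested
    cross-validation with Cohen's kappa and ROC analysis, and a seeded
    synthetic-EEG cohort generator so the whole pipeline can be exercised
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
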