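Package: radformal
Title: Radiomic Feature Verification for Soft-Tissue Sarcoma Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts metastasis and local-recurrence risk in soft-tissue
    sarcoma from fluid-sensitive MRI by combining per-slice radiomic feature
    extraction (first-order intensity statistics and 2D shape descriptors)
    with formal verification. Continuous features are discretized into three
    equal-width levels, translated into Calculus of Communicating Systems
    (CCS) action chains, and model-checked against modal mu-calculus disease
    properties by least-fixpoint iteration. Includes classification metrics
    with clinical utility indices, slice-level localization of satisfied
    properties, and a synthetic cohort generator for end-to-end evaluation
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
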