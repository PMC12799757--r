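Package: hsibruise
Title: Hematoma Age Estimation from Hyperspectral Skin Reflectance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for estimating the age of skin hematomas (bruises) from
    hyperspectral reflectance recordings in the 400-1000 nm range. Provides
    ENVI cube input/output with white-reference calibration and ROI mean-
    spectrum extraction, skin-referenced normalization (raw, skin-subtracted,
    skin-divided), L1-regularized (Lasso) age regression with plain,
    hierarchical (day-7 gated) and sex-stratified architectures,
    leave-one-subject-out cross-validation with RMSE and per-subject
    deviation reporting, and a Beer-Lambert chromophore-kinetics simulator
    that generates study-shaped synthetic datasets for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
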