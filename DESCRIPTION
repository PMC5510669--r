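Package: mwtriage
Title: Subspace Classification of Multi-Antenna Microwave Measurements for
    Intracranial Hematoma Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic-accuracy analysis of multi-antenna microwave
    scattering measurements aimed at pre-hospital screening for intracranial
    hematoma. Provides the antenna-channel combinatorics and channel-exclusion
    masks of an eight-antenna head array, a synthetic generator of triplicate
    complex scattering-parameter cohorts with a planted volume-scaled hematoma
    contrast, preprocessing into complex feature vectors, a rank-truncated
    subspace (SVD) classifier with projection-residual decision values,
    leave-one-out cross-validation with ROC/AUC and specificity at full
    sensitivity, model selection over frequency intervals and subspace ranks,
    resampling analyses (random subject removal and label-permutation null),
    and patient-characteristics cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
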