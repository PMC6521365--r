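Package: cohortqc
Title: Multivariate Outlier Detection for Data Quality Evaluation in Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data quality evaluation toolkit for participants-by-variables
    study tables. Detects multivariate outliers with a fast minimum covariance
    determinant (MCD) pipeline and a sparsity-targeted robust principal
    component analysis (RPCA) pipeline, explains each flagged participant via
    ranked contributing variables (corr-max partition for the MCD, sparse-matrix
    entries for the RPCA), compares sensitivity against univariate detectors
    (univariate MCD and boxplot fences), compiles cross-method verification
    lists, and drives the iterate-until-static error-correction loop. Includes
    a synthetic cohort generator with ground-truth error injection
    (transcription, miscomputed transformed scores, block-wise miscounts) so
    every detector can be benchmarked without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
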