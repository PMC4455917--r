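Package: mechsig
Title: Mechanism-Strength Transcriptome Classifiers for Anti-TNF Non-Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts non-response to anti-TNF therapy in rheumatoid arthritis
    from pre-treatment blood transcriptomes. Scores prior-knowledge signed
    gene sets ("mechanisms") on median-referenced log2 expression, fits a
    rescaled and thresholded lasso logistic classifier on the mechanism
    strength scores, and evaluates it with batch-balanced repeated k-fold,
    leave-one-batch-out and leave-one-sample-out cross-validation plus a
    label-permutation null. Includes EULAR DAS28 response calling, a DAS28
    measurement-noise simulation bounding achievable classifier AUROC,
    clustering-based re-implementations of previously published gene-list
    signatures, exact binomial and likelihood-ratio confidence intervals,
    and a synthetic multi-cohort data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
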