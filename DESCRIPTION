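Package: dermaclock
Title: Construction and Application of Skin-Specific DNA Methylation Age Clocks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building and applying skin-specific DNA methylation
    (DNAm) age predictors from beta-value matrices. Implements quantile
    normalization of beta values, probe filtering (cross-reactive,
    off-platform, sex-chromosome) with full accounting, ensemble feature
    selection combining penalized regression, gradient boosting and random
    forest importances with Pearson age correlation, age-balanced train/test
    splitting, k-fold cross-validated training of five learner families with
    RMSE-based model selection, DNAm age prediction with age-acceleration
    residuals, probe-level interpretation (loess R-squared importance,
    genomic region summaries, multi-clock probe overlaps), group-comparison
    statistics for intervention studies, hypergeometric over-representation
    analysis against user-supplied gene sets, and a synthetic methylome
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    glmnet,
    xgboost,
    ranger,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
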