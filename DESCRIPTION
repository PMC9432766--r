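Package: polyboost
Title: Windowed Gradient-Boosted SNP Selection and Polygenic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Polygenic genotype-to-phenotype prediction with gradient boosted
    decision trees. Implements a sequential window-based SNP selection
    algorithm in which a chain of warm-started boosted models walks along the
    genome and aggregates feature importances, so that newly selected variants
    are decorrelated from signal already captured; depth-controlled boosted
    prediction models with optional gene-covariate interaction restriction; an
    L1-regularized linear baseline; validation-weighted model ensembling on
    the probability simplex; r-squared and ROC AUC metrics with subsampling
    and closed-form standard errors; linkage-disequilibrium diagnostics; and a
    phenotype simulator with controlled linear, pairwise-epistatic, covariate
    and noise components for validating epistasis detection. Reads and writes
    PLINK 1 binary genotype files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xgboost (>= 1.6),
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
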