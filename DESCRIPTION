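Package: refsig
Title: Recursive Ensemble Feature Selection for Case-Control Omics Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers minimal discriminative feature signatures from
    case/control omics matrices (mRNA expression, DNA methylation) by
    recursive ensemble feature selection (REFS): eight heterogeneous
    classifiers are fitted under stratified k-fold cross-validation, feature
    importances are aggregated with a Borda-count rank scheme, and the
    feature set is recursively reduced by 20% per iteration until the
    ensemble's global accuracy drops below a stop threshold. Includes
    repeated-run consensus signature selection, a univariate chi-squared
    baseline, signature evaluation (per-classifier accuracy, ROC/AUC,
    two-group MANOVA via Wilks' lambda), candidate-gene CpG restriction for
    methylation arrays, cross-platform signature transfer, a synthetic
    case/control data generator with planted signal, and readers for
    TSV matrices, GEO series-matrix files, and probe/CpG annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ranger,
    xgboost,
    glmnet,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
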