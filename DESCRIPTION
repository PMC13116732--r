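Package: breathomics
Title: Multiclass Breathomics Analysis and VOC Network Remodeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for exhaled-breath volatile organic compound
    (VOC) feature tables acquired by real-time mass spectrometry across
    multiple chronic lung disease groups.  Provides a
    SummarizedExperiment-derived container for participant-level m/z
    intensity profiles with clinical covariates, control-referenced robust
    normalization, stability-based feature selection using gradient-boosted
    trees with minority-class oversampling, one-vs-one multiclass ROC
    evaluation with Youden-index thresholds and bootstrap confidence
    intervals, nonparametric univariate group comparisons, and signed
    distance-correlation network construction with weighted centrality
    deviation analysis and maximal weighted clique detection.  A synthetic
    cohort generator with known ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    igraph,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
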