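Package: ntcplasso
Title: Dose-Volume Toxicity Modeling with Bootstrap LASSO Stability Selection
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Normal tissue complication probability (NTCP) modeling for
    thoracic radiotherapy toxicity endpoints (esophagitis, pneumonitis) from
    cumulative dose-volume histograms (DVH) and clinical covariates.
    Implements EQD2 linear-quadratic dose conversion, Dx/mean/max and
    fractional (per-treatment-day) dosimetric feature extraction, rank-based
    univariate screening (Spearman against ordinal CTCAE grades, Wilcoxon
    rank-sum between dichotomized groups), collinearity reduction by
    hierarchical clustering on Pearson correlation, stratified
    train/validation splitting, bootstrap LASSO logistic stability selection
    with per-replicate validation AUC, six-bin risk calibration, and a
    synthetic cohort generator with a known logistic ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
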