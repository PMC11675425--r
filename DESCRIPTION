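Package: mpgspls
Title: Multi-Polygenic Score Prediction of Peripartum Depression via NIPALS Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks hundreds of correlated polygenic risk scores (PRSs) by their
    joint contribution to a binary peripartum-depression outcome using
    single-response partial least squares (PLS) regression fitted with the
    NIPALS algorithm. Provides cross-validated selection of the number of
    latent components (7-fold by default), variable-importance-in-projection
    (VIP) scores with the conventional VIP > 1 selection rule, signed
    predictive weights and direction calls, per-category contribution
    summaries, ROC/AUC of the first latent variable, and a cohort comparison
    battery (pooled-variance t tests with Cohen's d, uncorrected Pearson
    chi-square with Cramer's V) computable from raw columns or printed
    summary statistics. A synthetic score-panel generator with
    block-correlated predictors and a sparse planted liability signal stands
    in for genotype-derived PRS matrices, making the whole pipeline testable
    without real genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
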