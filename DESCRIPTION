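Package: ebstage
Title: Event-Based Subtype and Stage Inference for Tabular Biomarker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pipeline for event-based disease progression
    modelling of high-dimensional tabular biomarker cohorts. Validates and
    preprocesses CSV/TSV/PSV inputs (schema checks, numeric enforcement,
    missingness filtering with k-nearest-neighbour imputation, interquartile
    outlier capping), reduces dimensionality with an ensemble
    stability-scored feature selection scheme (gradient-boosted trees,
    penalised logistic regression and random forests voting across
    cross-validation folds), fits a clustered event-based model of disease
    progression with expectation-maximisation and Markov chain Monte Carlo
    sampling of biomarker orderings, enforces safeguards against
    overparameterisation, and exports interpretable subject- and
    biomarker-level stage/subtype annotations together with ordinal and
    chi-squared evaluation reports. A synthetic cohort generator with
    planted orderings supports validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ggplot2,
    glmnet,
    ranger,
    xgboost,
    mclust,
    optparse,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
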