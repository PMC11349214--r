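Package: copdgraph
Title: Causal Graph Discovery and Markov Blanket Prediction of Incident COPD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies baseline variables directly linked to five-year loss of
    normal spirometry (GOLD 0 status) with mixed-data causal graph learning.
    A pairwise mixed graphical model (group-lasso penalized pseudolikelihood)
    proposes a sparse undirected skeleton, which an FCI-max search orients into
    a partial ancestral graph using likelihood-ratio conditional independence
    tests that allow for latent confounding. The Markov blanket of the outcome
    is extracted per fold inside a nested cross-validation over the test
    significance level, and the selected blanket feeds logistic, random forest
    and elastic net predictors compared by AUROC. A synthetic cohort generator
    with known causal ground truth (mixed continuous/categorical variables,
    latent confounders, a thresholded two-axis spirometric outcome, class
    imbalance and missingness) supports end-to-end validation, together with
    Gower-distance KNN imputation and SMOTE-NC rebalancing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
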