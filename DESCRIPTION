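Package: psvmatch
Title: Prognostic Signature Vector Matching and Weighted-Voting Survival
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-layer prognostic classification for survival cohorts:
    univariate optimal-cutoff dichotomization of continuous variables by
    minimal Cox-Wald p-value (one-dimensional data-driven grouping),
    multivariate risk stratification by statistically weighted voting of the
    univariate risk calls into an average weighted risk score with
    log-rank-optimized three-group thresholds, and personalized risk
    prediction by Euclidean matching of rank-weighted prognostic signature
    vectors to reference patients. Includes six prognostic-variable weight
    schemes, a multi-classifier voting ensemble (nearest-signature matching
    plus six classical learners under stratified cross-validation),
    Goodman-Kruskal gamma concordance, a seeded synthetic-cohort simulator
    with planted cutoffs and hazard structure, and the published 37-variable
    ovarian-cancer signature as a packaged fixture.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
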