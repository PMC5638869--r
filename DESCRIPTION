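Package: rifs
Title: Randomly Re-Started Incremental Feature Selection for Binary
    Classification of High-Dimensional Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature (biomarker) panel discovery for "large p, small n"
    two-class expression matrices.  Implements the unit algorithm sIFS(k, D)
    -- incremental selection of consecutively ranked features from start
    rank k, tolerating up to D consecutive cross-validated accuracy
    decreases -- and RIFS, which returns the best sIFS outcome over many
    randomly chosen start ranks.  Includes t-test, Wilcoxon rank-sum and
    ANOVA-F feature ranking, stratified randomly-seeded k-fold
    cross-validation maximised over five built-in classifiers, same-size
    filter baselines, a synthetic-data generator with planted marginally
    weak but jointly discriminative feature pairs, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
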