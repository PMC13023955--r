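Package: pmiclock
Title: Postmortem Interval Estimation from Small RNA Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for postmortem interval (PMI) estimation from
    small non-coding RNA data. Provides hierarchical annotation of collapsed
    small-RNA reads (tsRNA, rsRNA, ysRNA, miRNA, piRNA, snoRNA) with one-mismatch
    tolerance, class-level temporal testing and fuzzy c-means clustering of miRNA
    profiles, RIN-based PMI regression across organs, a two-stage multi-seed
    stability-selection procedure for qPCR biomarker panels with a cross-validated
    random-forest predictor, exogenous bacterial small-RNA detection with a
    negative-binomial Wald test, cross-kingdom miRNA seed-match target scanning,
    exact interventional Shapley attribution, and a synthetic-data generator that
    emulates the statistical structure of postmortem cardiac small-RNA studies so
    every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    glmnet,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ranger,
    withr
Config/testthat/edition: 3
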