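Package: ahrfsig
Title: Cross-Cohort Transcriptomic Signature Discovery by Bootstrap
    Stability Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers whole-blood gene-expression signatures of severe
    pediatric acute hypoxemic respiratory failure across two independent
    cohorts. Provides a synthetic twin-cohort generator with planted
    class-informative genes, expression preprocessing (quantile
    normalization, probe-to-gene collapsing, per-batch standardization,
    a Benjamini-Hochberg corrected differential-expression screen),
    bootstrap stability selection with L1-penalized logistic regression,
    intersection of top-ranked gene lists with incremental signature
    evaluation by leave-one-out cross-validated AUROC and AUPRC,
    hypergeometric over-representation analysis against GMT gene-set
    collections, and degree-based hub detection on SIF interaction
    networks, orchestrated by a single-seed reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    limma,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
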