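Package: txrestore
Title: Treatment-Efficiency Scoring of Transcriptional Restoration Toward a
    Healthy Baseline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how well drug treatments restore a diseased
    transcriptome to the healthy state. Given a normalized log2 expression
    matrix with a healthy baseline group, a disease group and one or more
    treatment groups, the package computes per-gene differential expression
    (ordinary or empirical-Bayes moderated t with Benjamini-Hochberg
    adjustment), selects disease-signature and extended altered gene sets by
    log-fold-change and adjusted-p thresholds, clusters signature genes by
    their log-fold-change profiles with Ward agglomerative clustering,
    reports per-cluster mean absolute distance from the healthy baseline,
    and scores functional gene-set categories by a log10 ratio of mean
    displacement from disease over mean displacement from health. Includes
    a seeded synthetic-data generator with known ground truth and a
    deterministic end-to-end pipeline with a checksummed run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
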