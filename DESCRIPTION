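Package: tfcascade
Title: Transcription Factor Regulatory Cascade Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds directed transcription-factor (TF) regulatory networks from
    STRING-style protein action tables, enumerates simple directed regulatory
    cascades from source TFs, ranks TFs by PageRank and classical centralities,
    performs hypergeometric pathway over-representation analysis with
    Benjamini-Hochberg false-discovery-rate control, assembles an attributed
    TF/pathway knowledge graph, scores candidate next-TF links with node2vec
    embeddings and edge-embedding operators, and compares survival between
    altered and unaltered patient groups with Kaplan-Meier and log-rank
    methods. A synthetic-data generator with planted ground truth makes every
    stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    survival,
    stats,
    utils,
    Rcpp,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
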