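Package: grnhubs
Title: Community Prediction of Hub Regulators in Gene Regulatory Networks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts hub regulators (high-outdegree transcription factors)
    from gene expression data by combining an ensemble of gene regulatory
    network inference methods. Six inference engines are included
    (absolute Pearson correlation, CLR, ARACNE, tree-ensemble importance,
    bootstrap elastic net, and stability selection over a lasso path).
    An edge-inclusion threshold is selected by maximising the agreement of
    regulator outdegrees between methods, and regulators are ranked by
    their average outdegree across methods. Also provides evaluation
    metrics against gold-standard networks (Pearson and Spearman
    correlation of outdegrees, normalised absolute error, HITS hub
    scores), an edge-rank averaging consensus network, a weighted
    correlation network (topological overlap / module eigengene)
    comparator for hub ranking, and a synthetic benchmark generator with
    planted hubs.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    glmnet,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
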