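Package: mirhubnet
Title: miRNA Coexpression Networks, Hub Ranking and Hub-mRNA Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of paired tumor/normal miRNA sequencing data
    in two patient age groups: TMM normalization, empirical-Bayes batch
    adjustment, moderated paired differential expression with BH false
    discovery control, hard-threshold coexpression network construction with
    a clustering-coefficient-versus-random-graph threshold criterion,
    Maximal Clique Centrality hub ranking, permutation-calibrated
    hub-miRNA/mRNA correlation, and hypergeometric overrepresentation of the
    correlated gene lists against GMT gene-set collections. Includes a
    synthetic-data generator that plants every structure the analysis
    assumes (differential expression, hub-centred coexpression modules,
    miRNA-correlated genes, enriched gene sets) together with the ground
    truth needed for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    sva,
    yaml
Config/testthat/edition: 3
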