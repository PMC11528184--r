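Package: modclust
Title: Modularity-Based Network Clustering with Metanode Graphs and
    Cluster Annotation Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions undirected networks (typically protein-protein
    interaction networks) into modules by greedy modularity optimization:
    agglomerative fusion with transfer refinement, a multi-level
    transfer-fusion (Louvain-style) algorithm, and an overlapping cluster
    generator seeded from clique-based class systems.  Builds the quotient
    (metanode) graph of a partition with inter-cluster and shared-node edge
    weights and exports it as GraphML or DOT.  Imports free-dialect node
    annotation files, and scores per-cluster annotation terms with a
    one-sided hypergeometric test, Benjamini-Hochberg correction across all
    cluster-term pairs, and a majority rule, producing cluster-list,
    cluster-analysis, term-analysis and node-list tables plus a cluster by
    term count matrix.  Includes seeded stochastic-block-model and
    planted-annotation generators so every step is testable without
    external data, and a command-line interface wiring the pipeline end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
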