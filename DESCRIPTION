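Package: herbnet
Title: Network-Efficiency-Based Target Prioritization for Herbal Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Network-pharmacology target prioritization for multi-component
    herbal formulas. Builds a targets-pathways-targets (TPT) network by
    one-mode projection of a bipartite target-pathway annotation, scores
    every target by Network Efficiency Decrease (NED) under a knockout
    perturbation model in which each affected pathway loses one member's
    share of efficacy and edge lengths grow as the reciprocal of edge
    efficacy, and compares the ranking against degree and betweenness
    centrality baselines. Also provides Veber oral-bioavailability
    screening of compound tables, hypergeometric pathway
    over-representation with Benjamini-Hochberg FDR control, a directed
    targets-pathways-diseases (TPD) indegree analysis, Spearman
    rank-correlation validation against literature co-occurrence counts,
    synthetic data generators for all stages, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
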