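Package: pathcent
Title: Centrality-Weighted Pathway Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topology-aware pathway enrichment in which pathways are directed
    networks of nodes (proteins, complexes, families, compounds, microRNAs),
    each node holding a set of member genes. Nodes are weighted by network
    centrality -- in/out-degree, directed shortest-path betweenness, and
    largest-reach centrality (the largest finite shortest-path length into or
    out of a node) -- and a pathway score is the sum of weights over
    differentially affected nodes. Significance is the tail probability of the
    score under a Bernoulli gene-perturbation null, estimated by Monte-Carlo
    simulation and, for small single-gene pathways, computed exactly by subset
    enumeration. Includes the Fisher's-exact over-representation baseline,
    Benjamini-Hochberg FDR reporting, and an Erdos-Renyi / Barabasi-Albert
    random-network simulation harness for characterising how network structure
    and centrality choice drive pathway significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
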