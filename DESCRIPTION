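Package: mnen
Title: Influential Spreader Identification via Multi-Order Neighbors and Exclusive Neighborhoods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Identifies influential spreader nodes in undirected, unweighted
    networks by a parameter-free centrality that combines a node's degree and
    k-shell index with the log-damped k-shell contributions of its neighbors'
    exclusive neighborhoods, weighted by a common-neighbor relevance term.
    Includes a discrete-time stochastic SIR simulator providing ground-truth
    spreading power, classical centrality baselines (degree, k-shell,
    closeness, betweenness, eigenvector, PageRank), rank-agreement statistics
    (pairwise Kendall tau with explicit tie handling, top-m Jaccard), seeded
    synthetic network generators, edge-list input/output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
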