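Package: disjointMotifs
Title: Disjoint Network Motif Discovery in Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Scalable discovery of network motifs in undirected biological
    networks (for example protein-protein interaction graphs) under
    edge-disjoint (F2) and node-disjoint (F3) frequency measures.  Motifs of
    arbitrary size are grown by iteratively joining already-discovered motif
    instances with instances of four basic building patterns (the 2-edge
    path, triangle, 3-star and 3-edge path).  Disjoint frequencies are
    obtained with a greedy maximum-independent-set heuristic on embedding
    overlap graphs; for the basic patterns the overlap degrees are computed
    algebraically from host-graph degrees and common-neighbour counts rather
    than by pairwise embedding comparisons.  Includes canonical-label filters
    (degree vector and distance/degree node labels) that avoid most subgraph
    isomorphism tests, motif-abundance z-scores against degree-preserving
    edge-shuffled null ensembles, and Barabasi-Albert generators for
    PPI-like synthetic networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, igraph, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'basic-patterns.R'
    'cli.R'
    'disjoint-counting.R'
    'disjointMotifs-package.R'
    'graph-core.R'
    'isomorphism.R'
    'join-engine.R'
    'significance.R'
    'synthetic-data.R'
    'utils.R'
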