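Package: wnetnull
Title: Null Models and Link Prediction in Weighted Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how topological structure and edge-weight organisation
    contribute to link prediction in weighted undirected networks.  Provides
    six local similarity indices (common neighbours, Adamic-Adar, resource
    allocation, and their weighted forms with a tunable weight exponent), a
    train/probe/non-edge evaluation protocol with AUC and precision, five
    degree-preserving null-model rewiring algorithms (1k randomisation,
    structure shuffling, weight shuffling, rich-club enhancement and
    destruction, strength-assortativity rewiring), strong/weak tie
    partitioning with subset-restricted scrambling, readers and writers for
    weighted edge lists and Pajek files, and seeded generators of synthetic
    scale-free networks with heavy-tailed weights and a planted
    topology-weight correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
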