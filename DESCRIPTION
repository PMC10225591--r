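Package: mnda
Title: Multiplex Network Differential Analysis for Microbial Co-Occurrence Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how the local interaction neighborhood of each microbial
    taxon changes over time or across conditions. Individual-specific
    co-occurrence networks are built by leave-one-out perturbation of a global
    association network (the LIONESS scheme), stacked into two-layer multiplex
    networks, and embedded in a joint low-dimensional space with a shallow
    encoder-decoder neural network trained to map direct-neighbor vectors onto
    fixed-length random-walk reach profiles. Per-taxon neighborhood dynamics are
    scored by the cosine distance between a taxon's layer embeddings, and used
    for taxa ranking, ensemble consensus clustering of taxa and individuals, and
    phenotype prediction with node-, edge- and dynamics-oriented feature views.
    Includes a planted-perturbation simulation benchmark with a
    Laplacian-eigenvector baseline and a synthetic two-time-point cohort
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
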