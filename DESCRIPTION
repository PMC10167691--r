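Package: boolomics
Title: Boolean Network Inference and Topology-Based Pathway Analysis from
    Multiomics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Learns executable Boolean models of prior-knowledge signaling
    pathways from combined transcriptomic, proteomic and phosphoproteomic
    abundance matrices, using a genetic algorithm plus a node-local exhaustive
    search that returns equivalent rule sets. Node influence is scored by
    in-silico knock-in versus knockout simulation, and topology-based pathway
    enrichment combines importance scores with contrast fold-changes,
    coefficients of variation and cross-layer evidence into pathway modulation
    scores with permutation-derived z-scores and Benjamini-Hochberg adjusted
    p-values. Reads and writes graphml networks, parses KEGG KGML, and ships a
    ground-truthed synthetic multiomics generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    xml2,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
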