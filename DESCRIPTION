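Package: tandemaaa
Title: Classification and Evolutionary Analysis of Tandem Double-AAA ATPases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative profile hidden Markov model pipeline for tandem
    double-AAA-domain (Cdc48 family, Type-II AAA) proteins. Builds and
    calibrates per-subgroup profile HMMs, locates D1/D2 domain envelopes and
    tandem architectures, scores AAA+ motif degeneracy (Walker A/B, Sensors,
    arginine finger, pore loop), reconciles similarity-graph clustering with
    phylogenetic clades into a unified D-domain subgroup classification, and
    infers ancestral gene-family repertoires (LECA set, lineage-specific
    losses and duplications) by Dollo parsimony. Ships a synthetic-data
    generator that evolves planted families on a species tree with controlled
    divergence, losses, duplications and motif degeneracies so that every
    pipeline stage is testable end to end without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
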