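Package: coexcompare
Title: Comparative Co-Expression Network Analysis Across Species
Version: 0.1.0
Authors@R: person("Core", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Compares bait-centered co-expression networks from multiple
    species at the gene-family level. Extracts k-step neighborhoods around
    bait genes, scores how many species networks each gene family occurs in,
    filters conserved cores, collapses gene networks to family-level graphs,
    builds a cross-species consensus ("ancestral") network with node and edge
    support counts, overlays the phylogenetic first appearance of each family,
    and tallies functional-annotation composition per conservation class.
    Includes a synthetic-data generator with a planted conserved core so the
    whole pipeline is testable without external downloads, plus a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
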