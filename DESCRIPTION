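Package: nlrevol
Title: Evolutionary Analysis of NBS-LRR Resistance-Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the evolution of plant NBS-LRR (NLR)
    disease-resistance gene families: architecture subclass classification
    (TNL, CNL', RPW8-CNL, XNL', RPW8-XNL) from domain-annotation tables,
    identity/coverage-threshold gene-family clustering, Nei-Gojobori (1986)
    Ka/Ks estimation with Jukes-Cantor correction, nucleotide diversity,
    Ks-based gene-duplication dating, neighbor-joining trees with bootstrap
    supports and classification of supported clades into species-specific
    and lineage-specific duplications, and screening of differentially
    expressed NLR genes with time-point clustering. Includes a synthetic-data
    generator that plants known divergence levels, duplication events,
    domain architectures and expression signals so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
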