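Package: utrkit
Title: Design, Verification and Screen Analysis for Cloned 3'UTR Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building and analysing genome-scale 3'UTR clone
    collections. Designs Gateway-tailed primer panels that anchor forward
    primers on each gene's STOP codon and reverse primers 150 nt downstream
    of the annotated transcript end, simulates touchdown PCR and predicts
    amplicons in silico, verifies Sanger-sequenced clones by seeded local
    alignment against the expected insert panel, analyses dual-luciferase
    (3'LIFE-style) reporter screens with replicate-paired repression
    indices and hit calling, and computes library quality-control
    statistics. Includes deterministic synthetic-fixture generators
    (mini-genomes, Sanger-like reads, luminescence plates) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
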