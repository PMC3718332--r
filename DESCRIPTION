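Package: plasticome
Title: Comparative Genome-Plasticity Analysis for Archaeal Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the plastic fraction of small circular
    prokaryotic (especially crenarchaeal) chromosomes: headline genome
    statistics, pan-genome ortholog families from reciprocal-best-hit
    clustering, CRISPR repeat-spacer array detection with protospacer
    matching and PAM inference, integrated mobile-element discovery via
    viral/plasmid-homolog window enrichment, tRNA-linked attachment-site
    scanning and atypical-codon-usage (CAG) clustering, IS element and MITE
    cataloguing, Z-curve and ACCA-bias replication-origin calling,
    Markov-model exceptional-word statistics, and core-genome divergence
    dating under a hyperthermophile molecular clock. A fully deterministic
    synthetic-genome generator plants every feature class with a machine
    readable truth table, so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
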