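Package: satkit
Title: Characterization of Satellite DNA Repeats from Shotgun and ChIP
    Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for similarity-based characterization of satellite DNA
    (tandem repeat) families from low-pass genome shotgun and CenH3 ChIP-seq
    reads. Provides a synthetic tandem-array genome and read simulator with
    planted abundances and ChIP enrichment factors; read trimming and quality
    filtering; best-hit read assignment to repeat consensus references with
    BLASTn-style local alignment scoring; genomic abundance and physical-size
    (Mbp/1C) estimation; ChIP/input enrichment-ratio calling of centromeric
    repeats; monomer sequence-composition statistics (AT content, strand
    asymmetry indices, Karlin-style di- and tri-nucleotide relative
    abundances); tandem-array validation utilities (periodicity estimation,
    dot-plot subrepeat detection, outward-facing primer design and in-silico
    PCR across array junctions); and replication-timing regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    methods,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
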