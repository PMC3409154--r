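Package: bicoidchip
Title: Conserved Bicoid-Motif Scanning and ChIP-qPCR Occupancy Quantification
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for locating evolutionarily conserved bicoid-class
    homeodomain core motifs (TAATCY) in multi-species genomic alignments,
    for quantifying transcription-factor occupancy from ChIP-qPCR threshold
    cycles using a null-genotype (mutant) background model with
    percent-genome-occupancy estimates and propagated errors, and for
    genotype-contrast expression analysis with signed fold changes and
    fold-scanning false-discovery-rate curves. Includes seeded synthetic-data
    generators for alignments, qPCR plates and expression matrices with known
    ground truth, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
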