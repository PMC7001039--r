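Package: phasinet
Title: Inference of Plant Small RNA Regulatory Networks from Small RNA
    and Degradome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects phasiRNA-producing (PHAS) loci from collapsed small
    RNA sequencing libraries by cross-library consensus, identifies the
    miRNA and phasiRNA triggers that set their phased registers using
    degradome (PARE) evidence, extracts and names canonical and
    non-canonical phasiRNAs, validates sRNA-transcript cleavage
    interactions with a weighted multi-library degradome score, and
    assembles the results into a bipartite directed regulatory network
    with structural and GO-slim functional analysis.  Includes a seeded
    synthetic-data generator that plants ground-truthed phasiRNA
    cascades, so every stage of the pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
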