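Package: hairpinr
Title: Design and Analysis of G:U Wobble and Mismatched Hairpin RNAi Constructs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing hairpin RNA (hpRNA) transgene constructs whose
    sense arm is modified to disrupt the inverted-repeat DNA structure while
    preserving the double-stranded RNA stem: full C-to-T conversion yielding
    G:U wobble base pairs, and patterned complement-substitution mismatch
    schemes. Includes cassette assembly with FASTA/GFF3 export, a
    nearest-neighbor RNA duplex free-energy model distinguishing Watson-Crick
    stacks, G:U wobble stacks and mismatch loop penalties, bisulfite
    methylation calling from Sanger trace peak heights with CG/CHG/CHH context
    assignment, McrBC digestion-ratio estimation, exact-match small-RNA read
    classification separating primary from secondary sense siRNAs, and seeded
    synthetic-data generators for targets, Dicer-like read sets and noisy
    trace tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
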