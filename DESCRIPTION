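Package: imutseq
Title: Mutation Profiling and Translocation Mapping at Induced DNA
    Double-Strand Breaks from Multiplexed Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying DNA double-strand-break (DSB) induced
    mutations from multiplexed amplicon deep sequencing of endonuclease-cut
    loci. Classifies raw read pairs by amplification-primer identity into
    correctly repaired (cis) and translocated (trans) molecules, parses
    samtools-dialect pileup text into per-nucleotide mutation profiles
    (substitutions by change, insertions, deletions by size class), annotates
    deletion events with break adjacency and junction microhomology to flag
    microhomology-mediated end-joining and polymerase-slippage products,
    computes damaged-undamaged and treatment-control per-nucleotide deltas,
    metagene profiles and per-locus summaries, simulates paired-end reads and
    pileups under a parameterised DSB mutation spectrum with a machine-readable
    truth table, and tunes short-read aligner parameters with a seeded genetic
    algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
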