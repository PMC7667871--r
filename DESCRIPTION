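Package: exoclip
Title: iCLIP Analysis of Exoribonuclease RNA Substrates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for individual-nucleotide resolution UV
    crosslinking and immunoprecipitation (iCLIP) analysis of an archaeal
    exoribonuclease: composite-barcode read preprocessing with PCR-duplicate
    collapsing and exact demultiplexing, an internal unique-best read mapper
    with stranded coverage tracks, detection of circular-RNA junctions in
    unmapped reads via permuted split fragments, detection of non-templated
    A-rich 3' tails, crosslink-site metagene profiling (gene deciles, operon
    units, boundary windows, motif window extraction), and iCLIP/RNA-Seq
    enrichment plus genome nucleotide-content statistics. Ships a synthetic
    data generator with planted ground truth so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
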