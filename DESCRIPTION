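Package: stallr
Title: RNA Polymerase II Stalling Index Quantification from ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies promoter-proximal pausing of RNA polymerase II from
    ChIP-seq data. Derives strand-aware windows around the transcription
    start site and over the gene body of each transcript, counts aligned
    reads in those windows, and computes the stalling index (SI = TSS/GB)
    and its reciprocal, the travelling ratio (TR = GB/TSS), applying a
    transcript-length filter and a peak-at-TSS filter before quantification.
    Includes readers for GTF/BED12 annotation and narrowPeak/BED peak calls,
    significance filtering and replicate pooling of peaks, a validated
    multi-assay sample-sheet model, and a synthetic-data generator that
    emulates RNAPII ChIP-seq with a known pausing fraction so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
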