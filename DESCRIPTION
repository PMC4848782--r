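Package: celseq2
Title: CEL-Seq2 Single-Cell RNA-Seq Processing: Barcode Design, UMI
    Demultiplexing, Collision-Corrected Molecule Counting and Spike-In QC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the computational stack of the CEL-Seq2 3'-tag
    single-cell RNA-seq protocol: design of cell barcodes under Hamming
    distance, GC-content and terminal-base constraints; paired-end
    demultiplexing that extracts the UMI and cell barcode from read 1 and
    attaches them to read 2 metadata; strand-specific union-mode feature
    counting with exact-UMI deduplication and binomial collision correction
    of molecule counts; and spike-in quality control (capture efficiency via
    the intercept of a log-log fit, squared coefficient of variation,
    high-variability gene selection, and detection-fraction curves). A
    built-in simulator generates ground-truthed reference, annotation, reads
    and alignments so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ShortRead,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    BiocGenerics,
    yaml,
    data.table,
    jsonlite,
    Matrix,
    stats,
    utils,
    tools,
    methods,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
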