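Package: peaktx
Title: Predicting Nascent Transcription at ATAC-seq Open Chromatin Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies ATAC-seq open chromatin regions (OCRs) as overlapping
    nascent transcription or not, from chromatin accessibility data alone.
    Each OCR is summarised in a fixed 1 kbp evaluation window by a hybrid
    per-nucleotide encoding that pairs the per-million-normalized ATAC-seq
    read depth with the underlying genomic sequence, and classified with a
    bidirectional gated recurrent unit (GRU) network whose nucleotide
    embedding is trained jointly.  Includes corpus construction from
    narrowPeak/bedGraph/FASTA inputs with transcription-call labeling, a
    Gaussian kernel-density odds-ratio baseline, leakage-free
    chromosome-hold-out (leave-one-out training) evaluation with ROC-AUC and
    weighted F1, meta-peak profiling, and a fully self-contained synthetic
    data generator with planted width, amplitude, motif and bidirectional
    nascent signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    data.table,
    jsonlite,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
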