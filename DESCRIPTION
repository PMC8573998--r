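Package: irquant
Title: Intron Retention Quantification and Differential Analysis for
    Short- and Long-Read RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies intron retention from coordinate-sorted RNA-seq
    alignments in a short-read mode (median intron depth, maximum of the
    donor- and acceptor-side splice counts) and a long-read mode (minimum
    intron depth, exactly spliced reads with jitter-tolerant boundary
    matching). Derives the intron catalog and per-intron exclusion masks
    from a GTF annotation, attaches reliability warnings to each call,
    filters false-positive candidates with a small one-dimensional
    convolutional network trained on long-read-derived labels, and tests
    differential intron retention between sample groups with a negative
    binomial GLM on intron and exon counts or an empirical delta-ratio
    test. A simulation module generates annotations, aligned reads and
    replicate-level result tables with known retention levels so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    DESeq2,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
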