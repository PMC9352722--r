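Package: rloopscape
Title: Genome-Wide R-Loop Landscape Analysis with HMM Peak Calling and
    GC-Skew Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping and interpreting co-transcriptional R-loops
    from DRIP-seq coverage. Implements a two-state Gaussian hidden Markov
    model for R-loop peak calling on binned coverage, a four-state
    nucleotide-emission hidden Markov model for GC-skew segmentation and
    promoter-anchored gene skew classification, GRO-seq RPKM transcription
    classes, single-label genomic feature annotation of peaks, and
    integrative analyses relating R-loop peaks to DNA double-strand-break
    junction classes, replication timing, promoter GC content and a second
    cell type, with hypergeometric gene-set enrichment and kappa-based term
    clustering. A fully deterministic synthetic-genome generator with
    planted ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
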