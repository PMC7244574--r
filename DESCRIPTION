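Package: tifiso
Title: Transcript Isoform Clustering and Promoter-Proximal RNA Analysis
    from Paired 5'/3' End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for transcript isoform sequencing (TIF-seq) style data,
    where the capped 5' end (TSS) and the polyadenylation site (PAS) of the
    same RNA molecule are observed as a genomic end-pair. Implements
    two-dimensional single-linkage clustering of end-pairs into TIF-clusters,
    read-support and genomic poly(A) mispriming filters, TSS-support
    filtering, isoform category classification against a gene annotation,
    short promoter-proximal RNA (sppRNA) calling, nascent-transcription
    promoter-proximal pausing metrics with expression-matched control genes,
    metagene profiles, and IUPAC promoter motif scanning. A seeded simulator
    generates toy genomes, annotations, end-pair observations and coverage
    tracks with full ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    Rsamtools
Config/testthat/edition: 3
biocViews: Transcriptomics, Sequencing, GeneRegulation, Coverage
RoxygenNote: 7.3.3
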