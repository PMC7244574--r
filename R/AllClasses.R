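#' @import methods
#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
#' @importFrom BiocGenerics strand start end width
NULL

.validStrand <- function(gr) {
  s <- as.character(BiocGenerics::strand(gr))
  if (any(!s %in% c("+", "-")))
    return("strand must be '+' or '-' for every range")
  TRUE
}

#' End-pair observations from paired 5'/3' transcript end sequencing
#'
#' An \code{EndPairs} object holds one observed transcript molecule per range:
#' the capped 5' end and the last templated base before the poly(A) tail of
#' the same RNA, on a common chromosome and strand. The underlying
#' \linkS4class{GRanges} spans from the leftmost to the rightmost of the two
#' ends; \code{fivePrime()} and \code{threePrime()} recover the strand-aware
#' positions (on \code{+}, 5' = start and 3' = end; on \code{-} the reverse).
#'
#' @slot .Data inherited \code{GRanges} representation.
#' @seealso [EndPairs()], [fivePrime()], [threePrime()]
#' @exportClass EndPairs
setClass("EndPairs", contains = "GRanges")

setValidity("EndPairs", function(object) .validStrand(object))

#' TIF-clusters: merged TSS/PAS pairs with read support
#'
#' A \code{TIFCluster} groups end-pairs that share (within a merge window)
#' both a 5' and a 3' end. The range spans the representative TSS and PAS;
#' metadata columns carry \code{tss}, \code{pas} (strand-aware representative
#' positions), \code{support} (total contributing read pairs) and, after
#' classification, \code{gene_id}, \code{antisense} and \code{category}.
#'
#' @slot .Data inherited \code{GRanges} representation.
#' @seealso [buildPreclusters()], [mergePreclusters()], [classifyClusters()]
#' @exportClass TIFClusters
setClass("TIFClusters", contains = "GRanges")

setValidity("TIFClusters", function(object) {
  msg <- .validStrand(object)
  if (!isTRUE(msg)) return(msg)
  mc <- S4Vectors::mcols(object)
  need <- c("tss", "pas", "support")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    return(paste("missing metadata column(s):", paste(miss, collapse = ", ")))
  if (length(object)) {
    if (any(mc$support < 1L)) return("support must be >= 1")
    s <- as.character(BiocGenerics::strand(object))
    bad <- ifelse(s == "+", mc$tss > mc$pas, mc$pas > mc$tss)
    if (any(bad)) return("tss/pas ordering inconsistent with strand")
  }
  TRUE
})

#' Stranded per-base nascent-transcription coverage
#'
#' Holds one nonnegative per-base signal vector per chromosome and strand
#' (as run-length encoded \code{RleList}s), e.g. pNET-seq RNAPII occupancy.
#' \code{totalSignal()} returns the genome-wide sum used for library-size
#' normalisation.
#'
#' @slot plus,minus \code{SimpleRleList}, one numeric Rle per chromosome.
#' @seealso [CoverageTrack()], [readCoverage()], [pausingIndex()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
         representation(plus = "SimpleRleList", minus = "SimpleRleList"))

setValidity("CoverageTrack", function(object) {
  for (sl in list(object@plus, object@minus)) {
    if (length(sl) && any(vapply(sl, function(r) any(S4Vectors::runValue(r) < 0),
                                 logical(1))))
      return("coverage values must be nonnegative")
  }
  TRUE
})

#' Pipeline parameters
#'
#' All numeric constants of the clustering/classification/sppRNA pipeline in
#' one validated object. Defaults follow the TIF-seq analysis conventions:
#' end-pairs merge when both ends co-occur within a strict 20 nt window,
#' clusters need at least 3 supporting read pairs, genomic A-runs of >= 6 nt
#' within +/- 10 nt of the PAS flag 3' mispriming, sppRNAs are clusters
#' < 350 nt starting within +/- 40 nt of an annotated TSS, gene bodies are
#' shrunk 200 nt from each boundary, and the 5' pausing index uses a
#' +/- 150 nt promoter window against a 300 nt-shrunk gene body restricted
#' to non-overlapping genes > 1000 nt in the top 75% by expression.
#'
#' @param merge_window,min_support,polya_min_run,polya_scan_flank numerics,
#'   see description.
#' @param spprna_max_len,tss_flank,genebody_shrink numerics, see description.
#' @param pi_promoter_halfwidth,pi_body_shrink,pi_min_gene_len,pi_expr_fraction
#'   pausing-index settings.
#' @param size_dist_max width cutoff (strict) for size distributions.
#' @param tss_support_flank flank added to TSS-support intervals.
#' @param category_tolerance boundary tolerance (nt) separating "full span"
#'   from internal/extended categories.
#' @param random_seed integer seed recorded for reproducibility.
#' @return A \code{PipelineParams} object.
#' @examples
#' p <- PipelineParams(min_support = 2)
#' p@min_support
#' @export PipelineParams
#' @exportClass PipelineParams
PipelineParams <- setClass("PipelineParams", representation(
  merge_window = "numeric", min_support = "numeric",
  polya_min_run = "numeric", polya_scan_flank = "numeric",
  spprna_max_len = "numeric", tss_flank = "numeric",
  genebody_shrink = "numeric", pi_promoter_halfwidth = "numeric",
  pi_body_shrink = "numeric", pi_min_gene_len = "numeric",
  pi_expr_fraction = "numeric", size_dist_max = "numeric",
  tss_support_flank = "numeric", category_tolerance = "numeric",
  random_seed = "numeric"),
  prototype(
    merge_window = 20, min_support = 3, polya_min_run = 6,
    polya_scan_flank = 10, spprna_max_len = 350, tss_flank = 40,
    genebody_shrink = 200, pi_promoter_halfwidth = 150,
    pi_body_shrink = 300, pi_min_gene_len = 1000, pi_expr_fraction = 0.75,
    size_dist_max = 6000, tss_support_flank = 10, category_tolerance = 100,
    random_seed = 1))

setValidity("PipelineParams", function(object) {
  lens <- c(object@merge_window, object@min_support, object@polya_min_run,
            object@polya_scan_flank, object@spprna_max_len, object@tss_flank,
            object@genebody_shrink, object@pi_promoter_halfwidth,
            object@pi_body_shrink, object@pi_min_gene_len,
            object@size_dist_max, object@tss_support_flank,
            object@category_tolerance)
  if (any(!is.finite(lens)) || any(lens <= 0))
    return("all length/count parameters must be strictly positive")
  if (object@pi_expr_fraction <= 0 || object@pi_expr_fraction > 1)
    return("pi_expr_fraction must lie in (0, 1]")
  TRUE
})

#' The eight isoform category labels
#' @export
isoformCategories <- function() {
  c("full_span", "internal_initiation", "internal_termination",
    "internal_both", "five_prime_extended", "three_prime_extended",
    "antisense", "intergenic")
}
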