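#' Strand-aware 5' position of each element
#' @param x an \code{EndPairs} or \code{TIFClusters} object
#' @return integer vector of genomic positions
#' @export
setGeneric("fivePrime", function(x) standardGeneric("fivePrime"))

#' Strand-aware 3' position of each element
#' @param x an \code{EndPairs} or \code{TIFClusters} object
#' @return integer vector of genomic positions
#' @export
setGeneric("threePrime", function(x) standardGeneric("threePrime"))

#' Read-pair support of each cluster
#' @param x a \code{TIFClusters} object
#' @return integer vector
#' @export
setGeneric("clusterSupport", function(x) standardGeneric("clusterSupport"))

#' Total signal stored in a coverage track
#' @param x a \code{CoverageTrack}
#' @return numeric scalar, the genome-wide sum of per-base signal
#' @export
setGeneric("totalSignal", function(x) standardGeneric("totalSignal"))

setMethod("fivePrime", "EndPairs", function(x) {
  ifelse(as.character(strand(x)) == "+", start(x), end(x))
})
setMethod("threePrime", "EndPairs", function(x) {
  ifelse(as.character(strand(x)) == "+", end(x), start(x))
})
setMethod("fivePrime", "TIFClusters", function(x) S4Vectors::mcols(x)$tss)
setMethod("threePrime", "TIFClusters", function(x) S4Vectors::mcols(x)$pas)
setMethod("clusterSupport", "TIFClusters", function(x) S4Vectors::mcols(x)$support)

setMethod("totalSignal", "CoverageTrack", function(x) {
  s <- function(rl) if (length(rl)) sum(vapply(rl, function(r) sum(as.numeric(r)), numeric(1))) else 0
  s(x@plus) + s(x@minus)
})

setMethod("show", "EndPairs", function(object) {
  cat("EndPairs with", length(object), "molecule end-pair(s)\n")
  callNextMethod()
})

setMethod("show", "TIFClusters", function(object) {
  cat("TIFClusters with", length(object), "cluster(s)")
  if (length(object))
    cat("; total support", sum(clusterSupport(object)))
  cat("\n")
  callNextMethod()
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack on", length(union(names(object@plus), names(object@minus))),
      "chromosome(s); total signal", format(totalSignal(object)), "\n")
})

setMethod("show", "PipelineParams", function(object) {
  cat("PipelineParams:\n")
  for (sn in slotNames(object))
    cat(sprintf("  %-22s %s\n", sn, format(slot(object, sn))))
})
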