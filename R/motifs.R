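#' Named promoter-window presets
#'
#' Window extents (nt upstream / downstream of the TSS anchor) used for
#' promoter cis-element analyses: \code{"heatmap"} (200/150, the display
#' window for GAGA-box and TCP-motif heatmaps), \code{"promoter"} (300/50)
#' and \code{"downstream"} (20/250), the discovery windows.
#'
#' @param name one of \code{"heatmap"}, \code{"promoter"},
#'   \code{"downstream"}.
#' @return Named numeric vector \code{c(upstream=, downstream=)}.
#' @export
motifWindowPreset <- function(name = c("heatmap", "promoter", "downstream")) {
  switch(match.arg(name),
         heatmap = c(upstream = 200, downstream = 150),
         promoter = c(upstream = 300, downstream = 50),
         downstream = c(upstream = 20, downstream = 250))
}

#' Extract strand-oriented TSS-anchored sequence windows
#'
#' For each anchor, the genomic sequence covering \code{upstream} nt 5' and
#' \code{downstream} nt 3' of the anchor, oriented in the direction of
#' transcription (minus-strand windows are reverse-complemented, so
#' "upstream" is always 5' of the anchor). Windows running past chromosome
#' edges are padded with N. Anchors default to the annotated TSS; per-gene
#' measured TSS positions can be supplied instead.
#'
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param genes gene \code{GRanges}.
#' @param upstream,downstream window extents in nt; total length =
#'   \code{upstream + downstream}, with the anchor at 1-based offset
#'   \code{upstream + 1} (stored as attribute \code{"anchor_offset"}).
#' @param anchors optional integer vector of per-gene anchor positions
#'   (same order as \code{genes}); default = annotated TSS.
#' @return A named \code{DNAStringSet} (names = gene ids).
#' @export
extractPromoterWindows <- function(genome, genes, upstream, downstream,
                                   anchors = NULL) {
  if (is.null(anchors)) anchors <- annotatedTSS(genes)
  chrom <- as.character(GenomeInfoDb::seqnames(genes))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("genome lacks chromosome(s): ", paste(missing_chr, collapse = ", "))
  plus <- as.character(strand(genes)) == "+"
  # forward-strand extraction interval; length upstream + downstream
  st <- ifelse(plus, anchors - upstream, anchors - downstream + 1L)
  en <- ifelse(plus, anchors + downstream - 1L, anchors + upstream)
  out <- character(length(genes))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    len <- Biostrings::nchar(genome[[chr]])
    cst <- pmax(1L, st[i]); cen <- pmin(len, en[i])
    seqs <- as.character(Biostrings::extractAt(
      genome[[chr]], IRanges(cst, pmax(cen, cst - 1L))))
    padL <- strrep("N", pmax(0L, 1L - st[i]))
    padR <- strrep("N", pmax(0L, en[i] - len))
    out[i] <- paste0(padL, seqs, padR)
  }
  res <- Biostrings::DNAStringSet(out)
  res[!plus] <- Biostrings::reverseComplement(res[!plus])
  names(res) <- genes$gene_id
  attr(res, "anchor_offset") <- upstream + 1L
  res
}

.checkIUPAC <- function(pattern) {
  ok <- strsplit(pattern, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
  if (!all(ok))
    stop("invalid IUPAC character(s) in pattern: ",
         paste(unique(strsplit(pattern, "")[[1]][!ok]), collapse = ", "))
  invisible(TRUE)
}

#' Scan an IUPAC motif over a sequence window
#'
#' Reports every (overlapping) start position where each pattern symbol's
#' IUPAC set contains the window base. N in the window matches nothing (the
#' subject is matched literally; only pattern degeneracy is expanded). Only
#' the given strand is scanned; to mirror paired motifs (e.g. HTGGGCY vs its
#' reverse complement RGCCCAW), scan the pattern and its
#' \code{\link[Biostrings]{reverseComplement}} separately.
#'
#' @param window a \code{DNAString}, \code{DNAStringSet} of length 1, or
#'   character scalar.
#' @param pattern IUPAC degenerate string, e.g. \code{"GAGAR"}.
#' @return Integer vector of 1-based match start offsets.
#' @examples
#' scanMotif("GAGAA", "GAGAR")    # 1
#' scanMotif("AGCCCAT", "RGCCCAW")  # 1
#' @export
scanMotif <- function(window, pattern) {
  .checkIUPAC(pattern)
  if (is.character(window)) window <- Biostrings::DNAString(window)
  if (methods::is(window, "DNAStringSet")) window <- window[[1L]]
  start(Biostrings::matchPattern(pattern, window, fixed = "subject"))
}

#' Per-position motif frequency and per-window density
#'
#' For equal-length windows: \code{frequency[i]} is the fraction of windows
#' with a match starting at offset i; the per-window density is match count
#' divided by window length. Gene-set density comparisons go through
#' [compareDistributions()].
#'
#' @param windows an equal-length \code{DNAStringSet} (see
#'   [extractPromoterWindows()]).
#' @param pattern IUPAC degenerate string.
#' @return A list: \code{frequency} (length = window length),
#'   \code{density} (per window), \code{matrix} (windows x positions 0/1
#'   match-start indicators), \code{n_windows}.
#' @export
motifDensity <- function(windows, pattern) {
  .checkIUPAC(pattern)
  L <- unique(Biostrings::width(windows))
  if (length(L) > 1L) stop("windows must all have the same length")
  if (length(windows) == 0L)
    return(list(frequency = numeric(0), density = numeric(0),
                matrix = NULL, n_windows = 0L))
  hits <- Biostrings::vmatchPattern(pattern, windows, fixed = "subject")
  starts <- IRanges::start(hits)
  mat <- matrix(0L, nrow = length(windows), ncol = L,
                dimnames = list(names(windows), NULL))
  for (i in seq_along(starts))
    if (length(starts[[i]])) mat[i, starts[[i]]] <- 1L
  list(frequency = colMeans(mat),
       density = vapply(starts, length, 1L) / L,
       matrix = mat, n_windows = length(windows))
}
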