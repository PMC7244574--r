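#' Collapse end-pairs into pre-clusters
#'
#' End-pairs overlapping exactly at both ends are merged: one pre-cluster per
#' distinct (chrom, strand, 5', 3') combination, with support equal to its
#' multiplicity.
#'
#' @param pairs an \linkS4class{EndPairs} object.
#' @return A \linkS4class{TIFClusters} object (tss/pas = the exact pair
#'   positions), sorted by chrom, strand, tss, pas.
#' @examples
#' ep <- EndPairs("chr1", c(100, 100, 100), c(600, 600, 601), rep("+", 3))
#' buildPreclusters(ep)
#' @export
buildPreclusters <- function(pairs) {
  if (length(pairs) == 0L)
    return(TIFClusters())
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(pairs)),
                  strand = as.character(strand(pairs)),
                  five = fivePrime(pairs), three = threePrime(pairs),
                  stringsAsFactors = FALSE)
  o <- order(d$chrom, d$strand, d$five, d$three, method = "radix")
  d <- d[o, , drop = FALSE]
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$strand[-1] != d$strand[-nrow(d)] |
                 d$five[-1] != d$five[-nrow(d)] |
                 d$three[-1] != d$three[-nrow(d)])
  grp <- cumsum(new_run)
  support <- tabulate(grp)
  u <- d[new_run, , drop = FALSE]
  TIFClusters(u$chrom, u$five, u$three, u$strand, support)
}

#' Merge pre-clusters whose both ends co-occur within a window
#'
#' Single-linkage transitive closure of the relation |dTSS| < merge_window
#' AND |dPAS| < merge_window (strict: distance 19 merges at the default,
#' 20 does not), computed per chromosome and strand. Merged support is the
#' sum of member supports. The representative TSS (resp. PAS) is the member
#' 5' (resp. 3') position carrying the highest read support, ties broken
#' towards the outermost (5'-most / 3'-most) position.
#'
#' @param preclusters a \linkS4class{TIFClusters} object from
#'   [buildPreclusters()].
#' @param merge_window merge window in nt (default 20, strict).
#' @param keepMembers if \code{TRUE}, attach the contributing
#'   (five, three, support) triples of each merged cluster as a list column.
#' @return A \linkS4class{TIFClusters} object sorted by chrom, strand, tss.
#' @examples
#' pc <- TIFClusters("chr1", c(100, 119), c(500, 519), c("+", "+"), c(2L, 1L))
#' mergePreclusters(pc)  # one cluster, support 3, tss 100, pas 500
#' @export
mergePreclusters <- function(preclusters, merge_window = 20,
                             keepMembers = FALSE) {
  if (merge_window <= 0) stop("merge_window must be positive")
  n <- length(preclusters)
  if (n == 0L) return(preclusters)
  chrom <- as.character(GenomeInfoDb::seqnames(preclusters))
  strd <- as.character(strand(preclusters))
  five <- fivePrime(preclusters)
  three <- threePrime(preclusters)
  supp <- clusterSupport(preclusters)
  key <- paste(chrom, strd, sep = "\r")
  out <- vector("list", length(unique(key)))
  gi <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    o <- idx[order(five[idx], three[idx], method = "radix")]
    comp <- .merge_components(five[o], three[o], as.integer(merge_window))
    gi <- gi + 1L
    out[[gi]] <- .aggregate_components(chrom[o], strd[o], five[o], three[o],
                                       supp[o], comp, keepMembers)
  }
  res <- do.call(rbind, out)
  o <- order(res$chrom, res$strand, res$tss, method = "radix")
  res <- res[o, , drop = FALSE]
  cl <- TIFClusters(res$chrom, res$tss, res$pas, res$strand, res$support)
  if (keepMembers) S4Vectors::mcols(cl)$members <- res$members
  cl
}

# Representative position per end: highest summed support, tie -> outermost.
.rep_pos <- function(pos, supp, strand_plus, outermost_min) {
  s <- rowsum(supp, pos)
  cand <- as.integer(rownames(s))[s == max(s)]
  # outermost: 5'-most on + is min; on - is max (and mirrored for the PAS)
  if (xor(strand_plus, !outermost_min)) min(cand) else max(cand)
}

.aggregate_components <- function(chrom, strd, five, three, supp, comp,
                                  keepMembers) {
  sp <- split(seq_along(comp), comp)
  plus <- strd[1L] == "+"
  tss <- integer(length(sp)); pas <- integer(length(sp))
  support <- integer(length(sp))
  for (i in seq_along(sp)) {
    m <- sp[[i]]
    support[i] <- sum(supp[m])
    tss[i] <- .rep_pos(five[m], supp[m], plus, outermost_min = TRUE)
    pas[i] <- .rep_pos(three[m], supp[m], plus, outermost_min = FALSE)
  }
  d <- data.frame(chrom = chrom[1L], strand = strd[1L], tss = tss, pas = pas,
                  support = support, stringsAsFactors = FALSE)
  if (keepMembers)
    d$members <- lapply(sp, function(m)
      data.frame(five = five[m], three = three[m], support = supp[m]))
  d
}

#' Keep clusters with sufficient read-pair support
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param min_support minimum total read pairs (default 3); clusters with
#'   support >= \code{min_support} are kept, the remainder discarded.
#' @return Filtered \linkS4class{TIFClusters}; the discarded count is
#'   attached as attribute \code{"discarded"}.
#' @export
filterSupport <- function(clusters, min_support = 3) {
  if (min_support < 1) stop("min_support must be >= 1")
  keep <- clusterSupport(clusters) >= min_support
  res <- clusters[keep]
  attr(res, "discarded") <- sum(!keep)
  res
}

#' Remove clusters produced by genomic poly(A) mispriming
#'
#' Oligo(dT) priming on genomic A-rich tracts creates artifactual 3' ends. A
#' cluster is discarded iff the sense-strand genomic sequence within
#' \code{polya_scan_flank} nt of its PAS contains a run of at least
#' \code{polya_min_run} consecutive A's (for minus-strand clusters this is a
#' T-run on the forward reference within the mirrored window). Windows are
#' truncated at chromosome ends.
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param genome a \link[Biostrings]{DNAStringSet} covering all cluster
#'   coordinates.
#' @param polya_min_run minimum A-run length (default 6; longer runs contain
#'   a 6-mer and are likewise discarded).
#' @param polya_scan_flank half-width of the scanned window around the PAS
#'   (default 10 nt).
#' @return Filtered \linkS4class{TIFClusters} (kept clusters unchanged), with
#'   attribute \code{"discarded"}.
#' @export
filterMispriming <- function(clusters, genome, polya_min_run = 6,
                             polya_scan_flank = 10) {
  if (length(clusters) == 0L) return(clusters)
  chrom <- as.character(GenomeInfoDb::seqnames(clusters))
  missing_chr <- setdiff(unique(chrom), names(genome))
  if (length(missing_chr))
    stop("genome lacks chromosome(s): ", paste(missing_chr, collapse = ", "))
  pas <- threePrime(clusters)
  plus <- as.character(strand(clusters)) == "+"
  bad <- logical(length(clusters))
  for (chr in unique(chrom)) {
    i <- which(chrom == chr)
    len <- Biostrings::nchar(genome[[chr]])
    win <- IRanges(pmax(1L, pas[i] - as.integer(polya_scan_flank)),
                   pmin(len, pas[i] + as.integer(polya_scan_flank)))
    seqs <- Biostrings::extractAt(genome[[chr]], win)
    a_run <- strrep("A", polya_min_run)
    t_run <- strrep("T", polya_min_run)
    hitA <- Biostrings::vcountPattern(a_run, seqs) > 0L
    hitT <- Biostrings::vcountPattern(t_run, seqs) > 0L
    bad[i] <- ifelse(plus[i], hitA, hitT)
  }
  res <- clusters[!bad]
  attr(res, "discarded") <- sum(bad)
  res
}

#' Remove clusters whose TSS lacks independent TSS-seq support
#'
#' TIF-seq TSS calls are biased towards genic 3' ends; clusters are therefore
#' kept only when their TSS falls within a same-strand TSS-support interval
#' (from TSS-seq peak calling) extended by \code{tss_support_flank} nt on
#' each side (boundary inclusive).
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param tss_support a stranded \code{GRanges} of TSS-support intervals.
#' @param tss_support_flank flank in nt added to each interval side
#'   (default 10).
#' @return Filtered \linkS4class{TIFClusters} with attribute
#'   \code{"discarded"}.
#' @export
filterTSSSupport <- function(clusters, tss_support, tss_support_flank = 10) {
  if (length(clusters) == 0L) return(clusters)
  if (length(tss_support) == 0L) {
    warning("empty TSS-support set: all ", length(clusters),
            " cluster(s) removed")
    res <- clusters[0]
    attr(res, "discarded") <- length(clusters)
    return(res)
  }
  tsspos <- GRanges(GenomeInfoDb::seqnames(clusters),
                    IRanges(fivePrime(clusters), width = 1L),
                    strand = strand(clusters))
  ext <- suppressWarnings(
    GenomicRanges::resize(tss_support,
                          width(tss_support) + 2L * as.integer(tss_support_flank),
                          fix = "center"))
  ext <- GenomicRanges::trim(ext)
  keep <- IRanges::overlapsAny(tsspos, ext, ignore.strand = FALSE)
  res <- clusters[keep]
  attr(res, "discarded") <- sum(!keep)
  res
}

#' Run the full end-pair to TIF-cluster pipeline
#'
#' Composition in analysis order: pre-clustering (exact both-end merge) ->
#' windowed both-end merge -> read-support filter -> genomic poly(A)
#' mispriming filter -> TSS-support filter.
#'
#' @param pairs an \linkS4class{EndPairs} object (replicates merged upstream).
#' @param genome a \link[Biostrings]{DNAStringSet}.
#' @param tss_support stranded \code{GRanges} of TSS-support intervals.
#' @param params a \linkS4class{PipelineParams} object.
#' @return A list with \code{clusters} (final \linkS4class{TIFClusters}) and
#'   \code{counts}, the per-stage cluster counts (named integer vector:
#'   pairs, preclusters, merged, support_filtered, mispriming_filtered,
#'   tss_filtered).
#' @export
runClusterPipeline <- function(pairs, genome, tss_support,
                               params = PipelineParams()) {
  pre <- buildPreclusters(pairs)
  merged <- mergePreclusters(pre, params@merge_window)
  supported <- filterSupport(merged, params@min_support)
  clean <- filterMispriming(supported, genome, params@polya_min_run,
                            params@polya_scan_flank)
  final <- filterTSSSupport(clean, tss_support, params@tss_support_flank)
  counts <- c(pairs = length(pairs), preclusters = length(pre),
              merged = length(merged), support_filtered = length(supported),
              mispriming_filtered = length(clean),
              tss_filtered = length(final))
  list(clusters = final, counts = counts)
}
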