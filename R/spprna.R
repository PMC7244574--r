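#' Call short promoter-proximal RNAs (sppRNAs)
#'
#' sppRNAs are capped, polyadenylated transcripts terminated shortly after
#' initiation. A final cluster is called iff (i) its width is strictly below
#' \code{spprna_max_len}, (ii) its TSS lies within \code{tss_flank} nt
#' (boundary inclusive) of the annotated TSS of a same-strand gene, and
#' (iii) its interval overlaps no annotated termination site (annotated PAS
#' of any gene; same strand by default, both strands with
#' \code{termination_strand = "both"}). When several gene TSS windows
#' contain the cluster TSS, the nearest annotated TSS wins.
#'
#' @param clusters final \linkS4class{TIFClusters}.
#' @param genes gene \code{GRanges}.
#' @param spprna_max_len strict width bound in nt (default 350).
#' @param tss_flank half-width of the annotated-TSS window (default 40 nt).
#' @param termination_strand \code{"sense"} (default) or \code{"both"}:
#'   which strands' annotated PASs veto a call.
#' @return A \linkS4class{TIFClusters} subset of \code{clusters} with
#'   metadata columns \code{gene_id} (host gene) and
#'   \code{dist_to_annotated_tss} (signed nt, positive = downstream).
#' @export
callSppRNA <- function(clusters, genes, spprna_max_len = 350, tss_flank = 40,
                       termination_strand = c("sense", "both")) {
  termination_strand <- match.arg(termination_strand)
  w <- abs(threePrime(clusters) - fivePrime(clusters)) + 1L
  cand <- which(w < spprna_max_len)
  if (length(cand) == 0L) return(.emptySppRNA(clusters))
  cl <- clusters[cand]

  tsspos <- GRanges(GenomeInfoDb::seqnames(cl),
                    IRanges(fivePrime(cl), width = 1L), strand = strand(cl))
  twin <- GRanges(GenomeInfoDb::seqnames(genes),
                  IRanges(pmax(1L, annotatedTSS(genes) - as.integer(tss_flank)),
                          annotatedTSS(genes) + as.integer(tss_flank)),
                  strand = strand(genes))
  hits <- GenomicRanges::findOverlaps(tsspos, twin, ignore.strand = FALSE)
  if (length(hits) == 0L) return(.emptySppRNA(clusters))
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  plus <- as.character(strand(genes))[s] == "+"
  dist <- ifelse(plus, fivePrime(cl)[q] - annotatedTSS(genes)[s],
                 annotatedTSS(genes)[s] - fivePrime(cl)[q])
  o <- order(q, abs(dist), method = "radix")
  first <- !duplicated(q[o])
  qi <- q[o][first]

  paspos <- GRanges(GenomeInfoDb::seqnames(genes),
                    IRanges(annotatedPAS(genes), width = 1L),
                    strand = strand(genes))
  veto <- IRanges::overlapsAny(GenomicRanges::granges(cl)[qi], paspos,
                               ignore.strand = (termination_strand == "both"))
  qi2 <- qi[!veto]
  res <- cl[qi2]
  S4Vectors::mcols(res)$gene_id <- genes$gene_id[s[o][first]][!veto]
  S4Vectors::mcols(res)$dist_to_annotated_tss <- dist[o][first][!veto]
  res
}

.emptySppRNA <- function(clusters) {
  res <- clusters[0]
  S4Vectors::mcols(res)$gene_id <- character(0)
  S4Vectors::mcols(res)$dist_to_annotated_tss <- integer(0)
  res
}

#' Gene-level sppRNA statistics
#'
#' @param calls sppRNA calls from [callSppRNA()].
#' @param expressed_genes character vector of expressed gene ids (genes with
#'   at least one sense-assigned final cluster; see [isoformsPerGene()]).
#' @return A list: \code{fraction} (expressed genes with >= 1 call, in
#'   [0, 1]), \code{median_width} (nt), \code{per_gene} (data.frame gene_id,
#'   n_calls, min_width).
#' @export
sppRNAGeneStats <- function(calls, expressed_genes) {
  if (length(expressed_genes) == 0L) stop("empty expressed gene set")
  ids <- S4Vectors::mcols(calls)$gene_id
  w <- abs(threePrime(calls) - fivePrime(calls)) + 1L
  tab <- table(ids)
  per_gene <- data.frame(gene_id = names(tab), n_calls = as.integer(tab),
                         min_width = as.integer(
                           vapply(split(w, ids), min, 1L)[names(tab)]),
                         row.names = NULL)
  list(fraction = mean(expressed_genes %in% ids),
       median_width = if (length(w)) stats::median(w) else NA_real_,
       per_gene = per_gene)
}

#' Label genes by sppRNA/mRNA behaviour across two conditions
#'
#' Genes where mRNA signal rises at least \code{fold}-fold while sppRNA
#' signal drops at least \code{fold}-fold show the pattern expected from
#' selective promoter-proximal termination; genes where both rise are
#' coinduced. A +1 pseudocount guards zero denominators.
#'
#' @param spprna_a,mrna_a,spprna_b,mrna_b matched per-gene nonnegative signal
#'   vectors in conditions a and b.
#' @param fold fold-change threshold (default 1.5).
#' @return Character vector of labels in \{\code{selective_termination},
#'   \code{coinduced}, \code{other}\}.
#' @export
compareConditions <- function(spprna_a, mrna_a, spprna_b, mrna_b, fold = 1.5) {
  vals <- cbind(spprna_a, mrna_a, spprna_b, mrna_b)
  if (any(vals < 0)) stop("signals must be nonnegative")
  r_mrna <- (mrna_b + 1) / (mrna_a + 1)
  r_spp <- (spprna_b + 1) / (spprna_a + 1)
  ifelse(r_mrna >= fold & r_spp <= 1 / fold, "selective_termination",
         ifelse(r_mrna >= fold & r_spp >= fold, "coinduced", "other"))
}

#' Export sppRNA calls as BED6
#'
#' One record per call; name = host gene id, score = read-pair support,
#' mirroring a deposited sppRNA coordinate table.
#'
#' @param calls sppRNA calls from [callSppRNA()].
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
writeSppRNABed <- function(calls, path) {
  gr <- GenomicRanges::granges(calls)
  gr$name <- S4Vectors::mcols(calls)$gene_id
  gr$score <- as.numeric(clusterSupport(calls))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
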