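#' Assign final TIF-clusters to genes
#'
#' Genome-wide cluster analyses consider only non-overlapping genes (genes
#' whose interval intersects another gene on either strand are excluded) to
#' avoid ambiguous assignments. Among non-overlapping genes intersecting the
#' cluster interval, the same-strand candidate with maximal overlap wins;
#' when only opposite-strand candidates intersect, the maximal-overlap
#' antisense gene is recorded with an antisense mark. Ties break towards the
#' leftmost gene for determinism.
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param genes gene \code{GRanges} from [readGeneAnnotation()].
#' @return \code{clusters} with metadata columns \code{gene_id} (NA when no
#'   candidate intersects) and \code{antisense} (logical).
#' @export
assignClustersToGenes <- function(clusters, genes) {
  cand <- genes[!genes$overlapsOtherGene]
  gene_id <- rep(NA_character_, length(clusters))
  antisense <- rep(FALSE, length(clusters))
  if (length(clusters) && length(cand)) {
    hits <- GenomicRanges::findOverlaps(clusters, cand, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      ov <- width(IRanges::pintersect(GenomicRanges::granges(clusters)[q],
                                      GenomicRanges::granges(cand)[s],
                                      ignore.strand = TRUE))
      sense <- as.character(strand(clusters))[q] == as.character(strand(cand))[s]
      # prefer sense hits, then larger overlap, then leftmost gene
      o <- order(q, !sense, -ov, start(cand)[s], method = "radix")
      first <- !duplicated(q[o])
      qi <- q[o][first]; si <- s[o][first]
      gene_id[qi] <- cand$gene_id[si]
      antisense[qi] <- !sense[o][first]
    }
  }
  S4Vectors::mcols(clusters)$gene_id <- gene_id
  S4Vectors::mcols(clusters)$antisense <- antisense
  clusters
}

# Signed interior distances of a cluster's ends to its gene's boundaries.
# Positive = interior to the gene, for both ends.
.boundary_dists <- function(clusters, genes) {
  gi <- match(S4Vectors::mcols(clusters)$gene_id, genes$gene_id)
  plus <- as.character(strand(genes))[gi] == "+"
  ann_tss <- annotatedTSS(genes)[gi]
  ann_pas <- annotatedPAS(genes)[gi]
  tss <- fivePrime(clusters); pas <- threePrime(clusters)
  dT <- ifelse(plus, tss - ann_tss, ann_tss - tss)
  dP <- ifelse(plus, ann_pas - pas, pas - ann_pas)
  list(dT = dT, dP = dP, gene_len = width(genes)[gi])
}

#' Classify TIF-clusters into isoform categories
#'
#' Eight mutually exclusive categories against annotated gene boundaries,
#' with an explicit tolerance \code{tau} (nt) separating "full span" from
#' internal/extended boundaries. With signed interior distances dT (cluster
#' TSS vs annotated TSS) and dP (cluster PAS vs annotated PAS; positive =
#' inside the gene): no assigned gene -> \code{intergenic}; antisense mark
#' -> \code{antisense}; dT > tau and dP <= tau -> \code{internal_initiation};
#' dP > tau and dT <= tau -> \code{internal_termination}; both > tau ->
#' \code{internal_both}; dT < -tau and |dP| <= tau ->
#' \code{five_prime_extended}; dP < -tau and |dT| <= tau ->
#' \code{three_prime_extended}; otherwise \code{full_span}.
#'
#' @param clusters a \linkS4class{TIFClusters} object with assignments from
#'   [assignClustersToGenes()].
#' @param genes gene \code{GRanges}.
#' @param tau category tolerance in nt (default 100, must be > 0).
#' @return \code{clusters} with a \code{category} factor column (levels
#'   [isoformCategories()]).
#' @export
classifyClusters <- function(clusters, genes, tau = 100) {
  if (tau <= 0) stop("tau must be positive")
  if (is.null(S4Vectors::mcols(clusters)$gene_id))
    clusters <- assignClustersToGenes(clusters, genes)
  n <- length(clusters)
  cat <- rep("full_span", n)
  gene_id <- S4Vectors::mcols(clusters)$gene_id
  anti <- S4Vectors::mcols(clusters)$antisense
  cat[is.na(gene_id)] <- "intergenic"
  cat[!is.na(gene_id) & anti] <- "antisense"
  sense <- which(!is.na(gene_id) & !anti)
  if (length(sense)) {
    d <- .boundary_dists(clusters[sense], genes)
    lab <- rep("full_span", length(sense))
    lab[d$dP < -tau & abs(d$dT) <= tau] <- "three_prime_extended"
    lab[d$dT < -tau & abs(d$dP) <= tau] <- "five_prime_extended"
    lab[d$dT > tau & d$dP > tau] <- "internal_both"
    lab[d$dP > tau & d$dT <= tau] <- "internal_termination"
    lab[d$dT > tau & d$dP <= tau] <- "internal_initiation"
    cat[sense] <- lab
  }
  S4Vectors::mcols(clusters)$category <- factor(cat, levels = isoformCategories())
  clusters
}

#' Gene-length-normalised boundary distances
#'
#' For every sense-assigned cluster, the signed distance of its TSS and PAS
#' to the annotated gene boundaries, divided by gene length (positive =
#' interior to the gene). This table underlies the 2-D TSS/PAS scatter view
#' of isoform heterogeneity. Antisense and intergenic clusters are excluded.
#'
#' @param clusters assigned \linkS4class{TIFClusters}.
#' @param genes gene \code{GRanges}.
#' @return A data.frame with columns \code{gene_id}, \code{d_tss_norm},
#'   \code{d_pas_norm}.
#' @export
boundaryDistanceTable <- function(clusters, genes) {
  if (is.null(S4Vectors::mcols(clusters)$gene_id))
    clusters <- assignClustersToGenes(clusters, genes)
  sense <- !is.na(S4Vectors::mcols(clusters)$gene_id) &
    !S4Vectors::mcols(clusters)$antisense
  cl <- clusters[sense]
  if (length(cl) == 0L)
    return(data.frame(gene_id = character(), d_tss_norm = numeric(),
                      d_pas_norm = numeric()))
  d <- .boundary_dists(cl, genes)
  if (any(d$gene_len <= 0)) stop("zero-length gene encountered")
  data.frame(gene_id = S4Vectors::mcols(cl)$gene_id,
             d_tss_norm = d$dT / d$gene_len,
             d_pas_norm = d$dP / d$gene_len)
}

#' Distinct isoforms per expressed gene
#'
#' An expressed gene is a gene with at least one sense-assigned final
#' cluster; its isoform count is the number of distinct final clusters
#' assigned to it.
#'
#' @param clusters assigned \linkS4class{TIFClusters}.
#' @param genes gene \code{GRanges}.
#' @return A list with \code{per_gene} (data.frame gene_id, n_isoforms) and
#'   \code{mean} (arithmetic mean; \code{NA} when no gene is expressed).
#' @export
isoformsPerGene <- function(clusters, genes) {
  if (is.null(S4Vectors::mcols(clusters)$gene_id))
    clusters <- assignClustersToGenes(clusters, genes)
  sense <- !is.na(S4Vectors::mcols(clusters)$gene_id) &
    !S4Vectors::mcols(clusters)$antisense
  ids <- S4Vectors::mcols(clusters)$gene_id[sense]
  if (length(ids) == 0L)
    return(list(per_gene = data.frame(gene_id = character(),
                                      n_isoforms = integer()),
                mean = NA_real_))
  tab <- table(ids)
  list(per_gene = data.frame(gene_id = names(tab),
                             n_isoforms = as.integer(tab),
                             row.names = NULL),
       mean = mean(as.integer(tab)))
}

#' Category proportions and cross-set log2 fold-change
#'
#' Proportions over all classified clusters per set; with two sets, the
#' per-category log2(prop_b / prop_a). Zero proportions are replaced by half
#' the minimum observable proportion of their set (0.5 / n clusters) before
#' the ratio, avoiding infinities.
#'
#' @param clusters_a classified \linkS4class{TIFClusters}.
#' @param clusters_b optional second classified set (e.g. a mutant).
#' @return A data.frame with columns \code{category}, \code{prop_a} and,
#'   when \code{clusters_b} is given, \code{prop_b}, \code{log2fc}.
#' @export
categorySummary <- function(clusters_a, clusters_b = NULL) {
  props <- function(cl) {
    cats <- S4Vectors::mcols(cl)$category
    if (is.null(cats)) stop("clusters must be classified first")
    as.numeric(table(factor(cats, levels = isoformCategories()))) / length(cl)
  }
  out <- data.frame(category = isoformCategories(), prop_a = props(clusters_a))
  if (!is.null(clusters_b)) {
    out$prop_b <- props(clusters_b)
    pa <- ifelse(out$prop_a == 0, 0.5 / length(clusters_a), out$prop_a)
    pb <- ifelse(out$prop_b == 0, 0.5 / length(clusters_b), out$prop_b)
    out$log2fc <- log2(pb / pa)
  }
  out
}

#' Cluster width distribution summary
#'
#' Clusters with width below \code{size_dist_max} (strict) are summarised:
#' median, quartiles, histogram, and 1.5 x IQR whisker bounds (the boxplot
#' convention used for width comparisons between genotypes).
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param size_dist_max strict upper width bound in nt (default 6000).
#' @param breaks passed to [graphics::hist()] (computed, not plotted).
#' @return A list: \code{widths}, \code{median}, \code{q1}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}, \code{histogram}, \code{n}.
#' @export
sizeDistribution <- function(clusters, size_dist_max = 6000, breaks = 50) {
  w <- abs(threePrime(clusters) - fivePrime(clusters)) + 1L
  w <- w[w < size_dist_max]
  if (length(w) == 0L)
    return(list(widths = integer(), median = NA_real_, q1 = NA_real_,
                q3 = NA_real_, whisker_low = NA_real_, whisker_high = NA_real_,
                histogram = NULL, n = 0L))
  q <- stats::quantile(w, c(.25, .5, .75), names = FALSE)
  iqr <- q[3] - q[1]
  list(widths = w, median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = max(min(w), q[1] - 1.5 * iqr),
       whisker_high = min(max(w), q[3] + 1.5 * iqr),
       histogram = graphics::hist(w, breaks = breaks, plot = FALSE),
       n = length(w))
}
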