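#' Construct an EndPairs object
#'
#' @param chrom character vector of chromosome names.
#' @param fivePrime,threePrime integer vectors of genomic 1-based positions of
#'   the capped 5' end and the last templated base before the poly(A) tail.
#' @param strand character vector of \code{"+"}/\code{"-"}.
#' @param seqinfo optional \link[GenomeInfoDb]{Seqinfo}.
#' @return An \linkS4class{EndPairs} object.
#' @examples
#' EndPairs("chr1", c(100, 250), c(600, 900), c("+", "-"))
#' @export
EndPairs <- function(chrom = character(), fivePrime = integer(),
                     threePrime = integer(), strand = character(),
                     seqinfo = NULL) {
  fivePrime <- as.integer(fivePrime)
  threePrime <- as.integer(threePrime)
  bad <- ifelse(strand == "+", fivePrime > threePrime, threePrime > fivePrime)
  if (any(bad))
    stop("end ordering inconsistent with strand for ", sum(bad), " pair(s)")
  gr <- GRanges(chrom,
                IRanges(pmin(fivePrime, threePrime), pmax(fivePrime, threePrime)),
                strand = strand)
  if (!is.null(seqinfo)) GenomeInfoDb::seqinfo(gr) <- seqinfo
  new("EndPairs", gr)
}

#' Construct a TIFClusters object
#'
#' @param chrom,strand character vectors.
#' @param tss,pas representative strand-aware 5'/3' positions (1-based).
#' @param support integer read-pair support, >= 1.
#' @param ... further metadata columns (e.g. \code{gene_id}, \code{category}).
#' @return A \linkS4class{TIFClusters} object; \code{width} is
#'   \code{|pas - tss| + 1}.
#' @export
TIFClusters <- function(chrom = character(), tss = integer(), pas = integer(),
                        strand = character(), support = integer(), ...) {
  tss <- as.integer(tss); pas <- as.integer(pas)
  gr <- GRanges(chrom, IRanges(pmin(tss, pas), pmax(tss, pas)), strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(tss = tss, pas = pas,
                                               support = as.integer(support), ...)
  new("TIFClusters", gr)
}

#' Construct a stranded CoverageTrack
#'
#' @param plus,minus named \code{RleList} (or coercible, e.g. the result of
#'   \code{\link[GenomicRanges]{coverage}}) of per-base signal per chromosome.
#' @return A \linkS4class{CoverageTrack}.
#' @export
CoverageTrack <- function(plus = IRanges::RleList(), minus = IRanges::RleList()) {
  new("CoverageTrack", plus = methods::as(plus, "SimpleRleList"),
      minus = methods::as(minus, "SimpleRleList"))
}

#' Read a gene annotation (GFF3 or BED) into gene models
#'
#' Only gene-level features are used: for GFF3, records of type \code{gene}
#' (transcript-level features are ignored); for BED, every record. Each gene
#' is flagged \code{overlapsOtherGene} when its interval intersects any other
#' gene on either strand, the restriction used to exclude ambiguous regions
#' from genome-wide cluster analyses.
#'
#' @param path a GFF3 (\code{.gff}/\code{.gff3}) or BED file.
#' @return A \code{GRanges}, one range per gene, with metadata columns
#'   \code{gene_id}, \code{overlapsOtherGene} and (when the GFF3 has CDS
#'   features) \code{cds_start}/\code{cds_end}.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t101\t500\t.\t+\t.\tID=g1",
#'   "chr1\tsrc\tgene\t901\t1400\t.\t-\t.\tID=g2"), gff)
#' readGeneAnnotation(gff)
#' @export
readGeneAnnotation <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- tryCatch(
    rtracklayer::import(path, format = fmt),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  cds <- NULL
  if (fmt == "GFF3") {
    type <- as.character(gr$type)
    cds <- gr[type == "CDS"]
    gr <- gr[type == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else NULL
  }
  if (length(gr) == 0L) stop("no gene features found in ", path)
  if (is.null(ids) || anyNA(ids))
    ids <- paste0("gene", seq_along(gr))
  genes <- GenomicRanges::granges(gr)
  genes$gene_id <- ids
  # either-strand intersection: strictest reading of the non-overlapping-genes rule
  genes$overlapsOtherGene <-
    GenomicRanges::countOverlaps(genes, genes, ignore.strand = TRUE) > 1L
  if (!is.null(cds) && length(cds)) {
    parent <- sub("\\..*$", "", vapply(cds$Parent, function(p)
      if (length(p)) p[[1]] else NA_character_, character(1)))
    hit <- GenomicRanges::findOverlaps(genes, cds, ignore.strand = FALSE)
    keep <- parent[S4Vectors::subjectHits(hit)] == genes$gene_id[S4Vectors::queryHits(hit)] |
      is.na(parent[S4Vectors::subjectHits(hit)])
    hit <- hit[keep]
    cs <- rep(NA_integer_, length(genes)); ce <- rep(NA_integer_, length(genes))
    if (length(hit)) {
      qs <- S4Vectors::queryHits(hit)
      cs[unique(qs)] <- vapply(split(start(cds)[S4Vectors::subjectHits(hit)], qs), min, 1L)
      ce[unique(qs)] <- vapply(split(end(cds)[S4Vectors::subjectHits(hit)], qs), max, 1L)
    }
    genes$cds_start <- cs; genes$cds_end <- ce
  }
  genes
}

#' Annotated, strand-aware gene boundaries
#'
#' @param genes a gene \code{GRanges} (see [readGeneAnnotation()]).
#' @return integer vector of annotated TSS (\code{annotatedTSS}) or PAS
#'   (\code{annotatedPAS}) positions.
#' @export
annotatedTSS <- function(genes)
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))

#' @rdname annotatedTSS
#' @export
annotatedPAS <- function(genes)
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))

#' Read deduplicated transcript end-pairs from BEDPE (or paired BAM)
#'
#' BEDPE records are reduced to (chrom, strand, 5' end, 3' end): mate 1 is the
#' 5' (cap-end) block, mate 2 the 3' (poly(A)-junction) block; the pair strand
#' is the strand of mate 1. Cross-chromosome pairs are dropped with a logged
#' count. BAM input (requires Rsamtools) takes properly paired, name-matched
#' records with the first-of-pair read as the 5' block.
#'
#' @param path BEDPE file (10+ tab-separated columns) or a paired-end BAM.
#' @return An \linkS4class{EndPairs} object; the number of dropped
#'   cross-chromosome pairs is attached as attribute \code{"dropped"}.
#' @export
readEndPairs <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) return(.readEndPairsBAM(path))
  tab <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#", quote = ""),
    error = function(e) stop("failed to parse BEDPE ", path, ": ",
                             conditionMessage(e)))
  if (ncol(tab) < 10L)
    stop("BEDPE needs >= 10 columns, found ", ncol(tab))
  s1 <- tab[[9L]]; s2 <- tab[[10L]]
  if (any(!s1 %in% c("+", "-")) || any(!s2 %in% c("+", "-")))
    stop("invalid strand field in BEDPE (must be '+' or '-')")
  cross <- tab[[1L]] != tab[[4L]]
  if (any(cross))
    message(sum(cross), " cross-chromosome pair(s) dropped")
  tab <- tab[!cross, , drop = FALSE]
  strand <- tab[[9L]]
  # BED blocks are 0-based half-open; the biological end positions are the
  # outermost bases: on + the 5' block start and the 3' block end.
  five <- ifelse(strand == "+", tab[[2L]] + 1L, tab[[3L]])
  three <- ifelse(strand == "+", tab[[6L]], tab[[5L]] + 1L)
  ep <- EndPairs(tab[[1L]], five, three, strand)
  attr(ep, "dropped") <- sum(cross)
  ep
}

.readEndPairsBAM <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("BAM input requires the Rsamtools package")
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "strand", "pos", "qwidth", "flag"),
    flag = Rsamtools::scanBamFlag(isPaired = TRUE, isUnmappedQuery = FALSE,
                                  hasUnmappedMate = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  first <- bitwAnd(b$flag, 64L) > 0L
  d <- data.frame(qname = b$qname, chrom = as.character(b$rname),
                  strand = as.character(b$strand), start = b$pos,
                  end = b$pos + b$qwidth - 1L, first = first,
                  stringsAsFactors = FALSE)
  m1 <- d[d$first, ]; m2 <- d[!d$first, ]
  idx <- match(m1$qname, m2$qname)
  unpaired <- is.na(idx)
  if (any(unpaired)) warning(sum(unpaired), " unpaired record(s) skipped")
  m1 <- m1[!unpaired, ]; m2 <- m2[idx[!unpaired], ]
  cross <- m1$chrom != m2$chrom
  if (any(cross)) message(sum(cross), " cross-chromosome pair(s) dropped")
  m1 <- m1[!cross, ]; m2 <- m2[!cross, ]
  five <- ifelse(m1$strand == "+", m1$start, m1$end)
  three <- ifelse(m1$strand == "+", m2$end, m2$start)
  ep <- EndPairs(m1$chrom, five, three, m1$strand)
  attr(ep, "dropped") <- sum(cross)
  ep
}

#' Read one strand of a bedGraph into per-base coverage
#'
#' @param path 4-column bedGraph (0-based half-open intervals).
#' @return A named \code{RleList} of per-base signal (one Rle per chromosome)
#'   suitable for [CoverageTrack()]. Negative values and overlapping
#'   intervals (ambiguous signal) are errors.
#' @export
readCoverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(methods::as(IRanges::RleList(), "SimpleRleList"))
  if (any(gr$score < 0)) stop("negative coverage value in ", path)
  if (!IRanges::isDisjoint(gr))
    stop("overlapping bedGraph intervals in ", path, " (ambiguous signal)")
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write / read TIF-clusters as a tab-separated table
#'
#' Columns: chrom, strand, tss, pas, width, support, plus any extra metadata
#' columns present (gene_id, category, ...). Coordinates are written 1-based
#' as stored. The round trip is lossless for coordinates, strands and
#' supports.
#'
#' @param clusters a \linkS4class{TIFClusters} object.
#' @param path output/input file.
#' @return \code{writeClusters} returns \code{path} invisibly;
#'   \code{readClusters} returns a \linkS4class{TIFClusters}.
#' @export
writeClusters <- function(clusters, path) {
  mc <- as.data.frame(S4Vectors::mcols(clusters))
  keep <- !vapply(mc, is.list, logical(1))
  d <- cbind(data.frame(chrom = as.character(GenomeInfoDb::seqnames(clusters)),
                        strand = as.character(strand(clusters)),
                        tss = mc$tss, pas = mc$pas,
                        width = abs(mc$pas - mc$tss) + 1L,
                        support = mc$support),
             mc[keep & !colnames(mc) %in% c("tss", "pas", "support")])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusters
#' @export
readClusters <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  extra <- d[setdiff(colnames(d),
                     c("chrom", "strand", "tss", "pas", "width", "support"))]
  do.call(TIFClusters, c(list(chrom = d$chrom, tss = d$tss, pas = d$pas,
                              strand = d$strand, support = d$support),
                         as.list(extra)))
}

#' Read a BED6 file of TSS-support intervals
#'
#' @param path BED file of TSS-seq peak intervals.
#' @return A stranded \code{GRanges}.
#' @export
readTSSSupport <- function(path) rtracklayer::import(path, format = "BED")
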