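# Sum per-base signal of a CoverageTrack over stranded windows. Windows are
# clipped to stored chromosome lengths; chromosomes absent from the track
# contribute zero signal.
.regionSums <- function(track, gr) {
  out <- numeric(length(gr))
  s <- as.character(strand(gr))
  for (str in c("+", "-")) {
    rl <- if (str == "+") track@plus else track@minus
    i <- which(s == str)
    if (length(i) == 0L) next
    chrom <- as.character(GenomeInfoDb::seqnames(gr))[i]
    for (chr in unique(chrom)) {
      j <- i[chrom == chr]
      if (!chr %in% names(rl)) next
      r <- rl[[chr]]
      st <- pmax(1L, start(gr)[j]); en <- pmin(length(r), end(gr)[j])
      ok <- st <= en
      if (any(ok))
        out[j[ok]] <- IRanges::viewSums(IRanges::Views(r, st[ok], en[ok]))
    }
  }
  out
}

# TPM over a set of regions: per-kb rate normalised to the per-kb-rate sum
# over the set, x 1e6. Regions with zero length get rate 0.
.tpm <- function(raw, len) {
  rate <- ifelse(len > 0, raw / (len / 1000), 0)
  tot <- sum(rate)
  if (tot == 0) return(rep(0, length(rate)))
  rate / tot * 1e6
}

#' Gene-body nascent signal
#'
#' Signal over the gene shrunk by \code{shrink} nt from each boundary
#' (downstream of the TSS and upstream of the PAS), reducing bias from
#' TSS- and PAS-proximal nascent-transcription peaks. Genes not longer than
#' \code{2 * shrink} are excluded (reason logged in the result).
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param genes gene \code{GRanges}.
#' @param shrink nt removed from each gene end (default 200).
#' @return A data.frame with \code{gene_id}, \code{raw_count}, \code{tpm}
#'   (TPM over the eligible gene set), \code{eligible}, \code{reason}.
#' @export
geneBodySignal <- function(track, genes, shrink = 200) {
  len <- width(genes)
  eligible <- len > 2 * shrink
  body <- GRanges(GenomeInfoDb::seqnames(genes),
                  IRanges(start(genes) + ifelse(eligible, shrink, 0L),
                          end(genes) - ifelse(eligible, shrink, 0L)),
                  strand = strand(genes))
  raw <- rep(NA_real_, length(genes))
  raw[eligible] <- .regionSums(track, body[eligible])
  tpm <- rep(NA_real_, length(genes))
  tpm[eligible] <- .tpm(raw[eligible], width(body)[eligible])
  data.frame(gene_id = genes$gene_id, raw_count = raw, tpm = tpm,
             eligible = eligible,
             reason = ifelse(eligible, "", "gene shorter than 2 x shrink"))
}

#' 5' promoter-proximal pausing index
#'
#' Ratio of promoter TPM (window of \code{promoter_halfwidth} nt up- and
#' downstream of the annotated TSS) to gene-body TPM (gene shrunk by
#' \code{body_shrink} nt at each end). Because both TPMs share the
#' normalising per-kb-rate sum, the index equals the ratio of per-kb rates
#' and is invariant to global track scaling. Eligible genes are
#' non-overlapping, longer than \code{min_gene_len} nt, and in the top
#' \code{expr_fraction} by gene-body raw signal; genes with zero body signal
#' get an undefined (NA) index.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param genes gene \code{GRanges} with \code{overlapsOtherGene}.
#' @param promoter_halfwidth default 150 nt.
#' @param body_shrink default 300 nt.
#' @param min_gene_len strict minimum gene length (default 1000 nt).
#' @param expr_fraction expression quantile kept (default 0.75, the 75% most
#'   expressed eligible genes).
#' @return A data.frame with \code{gene_id}, \code{pausing_index},
#'   \code{promoter_tpm}, \code{body_tpm}, \code{eligible}, \code{reason}.
#' @export
pausingIndex <- function(track, genes, promoter_halfwidth = 150,
                         body_shrink = 300, min_gene_len = 1000,
                         expr_fraction = 0.75) {
  len <- width(genes)
  eligible <- !genes$overlapsOtherGene & len > min_gene_len &
    len > 2 * body_shrink
  reason <- ifelse(genes$overlapsOtherGene, "overlaps another gene",
                   ifelse(len <= min_gene_len, "gene too short", ""))
  tss <- annotatedTSS(genes)
  prom <- GRanges(GenomeInfoDb::seqnames(genes),
                  IRanges(pmax(1L, tss - as.integer(promoter_halfwidth)),
                          tss + as.integer(promoter_halfwidth)),
                  strand = strand(genes))
  body <- GRanges(GenomeInfoDb::seqnames(genes),
                  IRanges(start(genes) + ifelse(eligible, body_shrink, 0L),
                          end(genes) - ifelse(eligible, body_shrink, 0L)),
                  strand = strand(genes))
  braw <- rep(NA_real_, length(genes))
  braw[eligible] <- .regionSums(track, body[eligible])
  # expression ranking: gene-body raw signal on this track
  if (any(eligible)) {
    cut <- stats::quantile(braw[eligible], 1 - expr_fraction, names = FALSE)
    lowexp <- eligible & braw < cut
    reason[lowexp] <- "below expression fraction"
    eligible <- eligible & !lowexp
  }
  praw <- rep(NA_real_, length(genes))
  praw[eligible] <- .regionSums(track, prom[eligible])
  prate <- praw / (width(prom) / 1000)
  brate <- braw / (width(body) / 1000)
  norm <- sum(prate[eligible], brate[eligible])
  ptpm <- ifelse(eligible & norm > 0, prate / norm * 1e6, NA_real_)
  btpm <- ifelse(eligible & norm > 0, brate / norm * 1e6, NA_real_)
  pi <- ifelse(eligible & !is.na(brate) & brate > 0, prate / brate, NA_real_)
  reason[eligible & !is.na(brate) & brate == 0] <- "zero gene-body signal"
  data.frame(gene_id = genes$gene_id, pausing_index = pi,
             promoter_tpm = ptpm, body_tpm = btpm,
             eligible = eligible & !is.na(pi), reason = reason)
}

# Run a block with a private, restorable RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Select expression-matched control genes
#'
#' Bins the target genes' body signal into \code{n_bins} quantile bins and
#' samples, per bin and without replacement, an equal number of candidate
#' genes whose signal falls in the bin, giving a control set with an equal
#' distribution of nascent gene-body transcription. Seeded and
#' bit-reproducible; bins with too few candidates are filled as far as
#' possible with a warning.
#'
#' @param target_signal named numeric vector (names = gene ids) of target
#'   genes' body signal.
#' @param candidate_signal named numeric vector for candidate genes
#'   (must exclude the targets, e.g. all genes without sppRNAs).
#' @param n_bins number of quantile bins (default 10).
#' @param seed integer seed.
#' @return Character vector of selected candidate gene ids.
#' @export
matchControlGenes <- function(target_signal, candidate_signal, n_bins = 10,
                              seed = 1) {
  if (length(candidate_signal) < length(target_signal))
    stop("fewer candidates (", length(candidate_signal),
         ") than targets (", length(target_signal), ")")
  br <- unique(stats::quantile(target_signal, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  if (length(br) < 2L) br <- c(br, br)
  br[1] <- -Inf; br[length(br)] <- Inf
  tbin <- cut(target_signal, br, labels = FALSE, include.lowest = TRUE)
  cbin <- cut(candidate_signal, br, labels = FALSE, include.lowest = TRUE)
  .with_seed(seed, {
    sel <- character(0)
    deficit <- 0L
    for (b in sort(unique(tbin))) {
      need <- sum(tbin == b)
      pool <- names(candidate_signal)[cbin == b]
      if (length(pool) < need) {
        deficit <- deficit + (need - length(pool))
        sel <- c(sel, pool)
      } else {
        sel <- c(sel, sample(pool, need))
      }
    }
    if (deficit > 0L)
      warning(deficit, " target gene(s) could not be matched (empty bins)")
    sel
  })
}

#' Metagene coverage profile around anchor points
#'
#' Strand-oriented windows of \code{[-flank, +flank]} around each anchor
#' (e.g. sppRNA PAS positions); per-position mean across anchors with a 95%
#' normal-approximation confidence band (mean +/- 1.96 x SEM). Windows
#' extending past a chromosome edge are dropped and counted.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param anchors stranded width-1 \code{GRanges} of anchor positions.
#' @param flank window half-width in nt.
#' @return A data.frame with \code{position} (-flank..flank, transcription
#'   direction), \code{mean}, \code{sem}, \code{ci_low}, \code{ci_high},
#'   \code{n_anchors}; the dropped-window count is attribute
#'   \code{"dropped"}.
#' @export
metageneProfile <- function(track, anchors, flank) {
  L <- 2L * as.integer(flank) + 1L
  s <- as.character(strand(anchors))
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  pos <- start(anchors)
  rows <- matrix(NA_real_, nrow = length(anchors), ncol = L)
  dropped <- 0L
  for (i in seq_along(anchors)) {
    rl <- if (s[i] == "+") track@plus else track@minus
    if (!chrom[i] %in% names(rl)) { dropped <- dropped + 1L; next }
    r <- rl[[chrom[i]]]
    st <- pos[i] - flank; en <- pos[i] + flank
    if (st < 1L || en > length(r)) { dropped <- dropped + 1L; next }
    v <- as.numeric(S4Vectors::window(r, st, en))
    if (s[i] == "-") v <- rev(v)
    rows[i, ] <- v
  }
  ok <- !is.na(rows[, 1L])
  n <- sum(ok)
  if (n == 0L) stop("no anchor window lies fully within the covered genome")
  m <- colMeans(rows[ok, , drop = FALSE])
  sem <- apply(rows[ok, , drop = FALSE], 2L, stats::sd) / sqrt(n)
  if (n == 1L) sem <- rep(0, L)
  out <- data.frame(position = seq(-flank, flank), mean = m, sem = sem,
                    ci_low = m - 1.96 * sem, ci_high = m + 1.96 * sem,
                    n_anchors = n)
  attr(out, "dropped") <- dropped
  out
}

#' Compare two signal distributions by rank-sum test
#'
#' Standard two-sided Wilcoxon rank-sum test with medians reported
#' alongside. Fully tied degenerate input returns p = 1 with a warning.
#'
#' @param values_a,values_b nonempty numeric vectors.
#' @return A list: \code{p_value}, \code{median_a}, \code{median_b},
#'   \code{n_a}, \code{n_b}.
#' @export
compareDistributions <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be nonempty")
  if (length(unique(c(values_a, values_b))) == 1L) {
    warning("all values tied; p set to 1")
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, alternative = "two.sided"))$p.value
  }
  list(p_value = p, median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       n_a = length(values_a), n_b = length(values_b))
}

#' Per-gene TPM in a window around the annotated PAS
#'
#' Full-length mRNA expression proxy: TPM over
#' \code{[PAS - halfwidth, PAS + halfwidth]}, normalised over the supplied
#' gene set. Feeds the sppRNA-vs-control distribution comparison via
#' [compareDistributions()].
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param genes gene \code{GRanges}.
#' @param halfwidth window half-width in nt.
#' @return A data.frame with \code{gene_id}, \code{raw_count}, \code{tpm}.
#' @export
tpmAtPAS <- function(track, genes, halfwidth) {
  pas <- annotatedPAS(genes)
  win <- GRanges(GenomeInfoDb::seqnames(genes),
                 IRanges(pmax(1L, pas - as.integer(halfwidth)),
                         pas + as.integer(halfwidth)),
                 strand = strand(genes))
  raw <- .regionSums(track, win)
  data.frame(gene_id = genes$gene_id, raw_count = raw,
             tpm = .tpm(raw, width(win)))
}
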