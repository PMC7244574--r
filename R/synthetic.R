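# Zero-truncated Poisson: rate giving a target truncated mean, and sampling.
.ztp_lambda <- function(mean_target) {
  if (mean_target <= 1) stop("zero-truncated Poisson mean must exceed 1")
  stats::uniroot(function(l) l / (1 - exp(-l)) - mean_target,
                 c(1e-8, 1e3), tol = 1e-10)$root
}

.rztp <- function(n, lambda) {
  u <- stats::runif(n, exp(-lambda), 1)
  stats::qpois(u, lambda)
}

#' Simulate a toy genome with gene annotation and planted A-tracts
#'
#' Alternating-strand genes with random uniform-base sequence, separated by
#' random intergenic spacers. Each gene carries (with probability
#' \code{a_tract_rate}) one planted sense-strand A-tract of 6-9 nt at a
#' recorded interior position (at least 360 nt from the TSS and 411 nt from
#' the PAS, so tracts never veto true transcript ends); on minus-strand
#' genes the tract is a T-run on the forward reference. Deterministic under
#' a fixed seed.
#'
#' @param n_genes number of genes (0 allowed: sequence only).
#' @param gene_len_range,intergenic_len_range integer ranges (nt), sampled
#'   uniformly.
#' @param a_tract_rate per-gene probability of a planted A-tract in [0, 1].
#' @param genes_per_chrom genes per simulated chromosome (default 500).
#' @param seed integer seed.
#' @return A list: \code{genome} (\code{DNAStringSet}), \code{genes}
#'   (\code{GRanges} with \code{gene_id}, \code{overlapsOtherGene}),
#'   \code{a_tracts} (\code{GRanges} with \code{gene_id}), \code{params}.
#' @export
simulateGenome <- function(n_genes = 2000, gene_len_range = c(1000, 3000),
                           intergenic_len_range = c(300, 800),
                           a_tract_rate = 1, genes_per_chrom = 500,
                           seed = 1) {
  if (any(gene_len_range <= 0) || any(intergenic_len_range <= 0))
    stop("length ranges must be positive")
  if (gene_len_range[1] < 1000)
    stop("gene_len_range minimum must be >= 1000 (isoform grid requires it)")
  .with_seed(seed, {
    chrom_of <- if (n_genes > 0)
      paste0("chrS", (seq_len(n_genes) - 1L) %/% genes_per_chrom + 1L)
      else character(0)
    chroms <- if (n_genes > 0) unique(chrom_of) else "chrS1"
    gene_len <- sample(gene_len_range[1]:gene_len_range[2], n_genes,
                       replace = TRUE)
    seqs <- character(length(chroms))
    gstart <- integer(n_genes); gend <- integer(n_genes)
    for (ci in seq_along(chroms)) {
      idx <- which(chrom_of == chroms[ci])
      inter <- sample(intergenic_len_range[1]:intergenic_len_range[2],
                      length(idx) + 1L, replace = TRUE)
      pos <- inter[1L]
      for (k in seq_along(idx)) {
        gstart[idx[k]] <- pos + 1L
        gend[idx[k]] <- pos + gene_len[idx[k]]
        pos <- gend[idx[k]] + inter[k + 1L]
      }
      clen <- if (length(idx)) pos else 10000L
      seqs[ci] <- paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                        collapse = "")
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    if (n_genes == 0L)
      return(list(genome = genome,
                  genes = GRanges(gene_id = character(0),
                                  overlapsOtherGene = logical(0)),
                  a_tracts = GRanges(gene_id = character(0)),
                  params = list(seed = seed)))
    strands <- rep(c("+", "-"), length.out = n_genes)
    genes <- GRanges(chrom_of, IRanges(gstart, gend), strand = strands)
    genes$gene_id <- sprintf("g%04d", seq_len(n_genes))
    genes$overlapsOtherGene <-
      GenomicRanges::countOverlaps(genes, genes, ignore.strand = TRUE) > 1L

    has_tract <- stats::runif(n_genes) < a_tract_rate
    ti <- which(has_tract)
    tlen <- sample(6:9, length(ti), replace = TRUE)
    # interior placement: >= 360 nt from the TSS, >= 411 nt from the PAS
    lo <- ifelse(strands[ti] == "+", gstart[ti] + 360L, gstart[ti] + 411L)
    hi <- ifelse(strands[ti] == "+", gend[ti] - 411L - tlen, gend[ti] - 360L - tlen)
    tpos <- lo + floor(stats::runif(length(ti)) * (hi - lo + 1L))
    for (k in seq_along(ti)) {
      base <- if (strands[ti[k]] == "+") "A" else "T"
      Biostrings::subseq(genome[[chrom_of[ti[k]]]],
                         tpos[k], tpos[k] + tlen[k] - 1L) <-
        Biostrings::DNAString(strrep(base, tlen[k]))
    }
    a_tracts <- GRanges(chrom_of[ti], IRanges(tpos, tpos + tlen - 1L),
                        strand = strands[ti])
    a_tracts$gene_id <- genes$gene_id[ti]
    list(genome = genome, genes = genes, a_tracts = a_tracts,
         params = list(n_genes = n_genes, gene_len_range = gene_len_range,
                       intergenic_len_range = intergenic_len_range,
                       a_tract_rate = a_tract_rate, seed = seed))
  })
}

# Candidate non-canonical isoform boundaries for one gene, on a 60 nt grid:
# internal initiation (interior TSS, canonical PAS) and internal termination
# (canonical TSS, interior PAS with width >= 420 nt so calls never look like
# sppRNAs).
.isoform_candidates <- function(gene_len) {
  tss_off <- seq.int(120L, max(120L, gene_len - 400L), by = 60L)
  pas_off <- seq.int(120L, max(120L, gene_len - 420L), by = 60L)
  pas_off <- pas_off[gene_len - pas_off >= 420L]
  rbind(data.frame(tss_off = tss_off, pas_off = 0L,
                   type = "internal_initiation"),
        if (length(pas_off))
          data.frame(tss_off = 0L, pas_off = pas_off,
                     type = "internal_termination"))
}

#' Simulate transcript end-pair observations with full ground truth
#'
#' Per gene, a zero-truncated Poisson number of isoforms (canonical full
#' span plus interior-boundary variants separated by >= 60 nt); a configured
#' fraction of genes additionally emits an sppRNA isoform starting within
#' +/- 10 nt of the annotated TSS with length drawn from a lognormal
#' (configurable median) truncated to [40, 349] nt. Molecules are allocated
#' multinomially by gamma-distributed gene expression and per-gene isoform
#' weights; observed ends are jittered by discretised zero-mean normal noise
#' (sd \code{dispersion}, clamped to 3 sd). Misprimed molecules have their
#' 3' end replaced by the position templated by the gene's planted A-tract
#' (unjittered: the priming site is genomic); artifact molecules carry an
#' unsupported 3'-biased 5' end. A TSS-support interval set (+/- 20 nt
#' around every true isoform TSS) is emitted alongside.
#'
#' @param sim result of [simulateGenome()].
#' @param mean_isoforms target mean isoforms per gene (zero-truncated
#'   Poisson; default 4.3).
#' @param tss_dispersion,pas_dispersion end-jitter sd in nt (default 5).
#' @param spprna_gene_fraction fraction of genes with an sppRNA isoform in
#'   [0, 1] (default 0.14).
#' @param spprna_length_median median of the lognormal sppRNA length model
#'   (default 93 nt).
#' @param spprna_length_sdlog lognormal sdlog (default 0.35).
#' @param spprna_weight per-gene molecule fraction emitted as sppRNA at
#'   sppRNA genes (default 0.3).
#' @param depth total number of molecules (default 200000).
#' @param mispriming_rate per-molecule mispriming probability (default 0.05;
#'   applies only at genes carrying a planted A-tract).
#' @param artifact_rate per-molecule probability of an artifactual
#'   unsupported 5' end (default 0.02).
#' @param seed integer seed.
#' @return A list: \code{pairs} (\linkS4class{EndPairs}, one per molecule),
#'   \code{isoforms} (truth data.frame: gene_id, isoform_id, chrom, strand,
#'   tss, pas, weight, type), \code{molecules} (truth data.frame: gene_id,
#'   isoform_id, misprimed, artifact, five, three), \code{tss_support}
#'   (\code{GRanges}), \code{spprna_genes} (character), \code{params}.
#' @export
simulateEndPairs <- function(sim, mean_isoforms = 4.3, tss_dispersion = 5,
                             pas_dispersion = 5, spprna_gene_fraction = 0.14,
                             spprna_length_median = 93,
                             spprna_length_sdlog = 0.35, spprna_weight = 0.3,
                             depth = 200000, mispriming_rate = 0.05,
                             artifact_rate = 0.02, seed = 1) {
  if (spprna_gene_fraction < 0 || spprna_gene_fraction > 1)
    stop("spprna_gene_fraction must lie in [0, 1]")
  genes <- sim$genes
  n <- length(genes)
  if (n == 0L) stop("simulated genome has no genes")
  .with_seed(seed, {
    lambda <- .ztp_lambda(mean_isoforms)
    k <- .rztp(n, lambda)
    plus <- as.character(strand(genes)) == "+"
    gl <- width(genes)
    ann_tss <- annotatedTSS(genes)
    ann_pas <- annotatedPAS(genes)
    chrom <- as.character(GenomeInfoDb::seqnames(genes))

    spp_genes <- sort(sample(n, round(spprna_gene_fraction * n)))
    is_spp <- seq_len(n) %in% spp_genes

    iso <- vector("list", n)
    for (g in seq_len(n)) {
      cand <- .isoform_candidates(gl[g])
      extra <- min(k[g] - 1L, nrow(cand))
      pick <- if (extra > 0L) cand[sample(nrow(cand), extra), , drop = FALSE]
        else cand[0, , drop = FALSE]
      d <- rbind(data.frame(tss_off = 0L, pas_off = 0L, type = "canonical"),
                 pick)
      w <- stats::rgamma(nrow(d), shape = 1)
      w[1L] <- max(w)  # canonical carries the dominant molecule
      d$weight <- w / sum(w)
      if (is_spp[g]) {
        t_off <- sample(-10:10, 1L)
        len <- 0L
        while (len < 40L || len > 349L)
          len <- round(stats::rlnorm(1, log(spprna_length_median),
                                     spprna_length_sdlog))
        d$weight <- d$weight * (1 - spprna_weight)
        d <- rbind(d, data.frame(tss_off = t_off, pas_off = NA_integer_,
                                 type = "spprna", weight = spprna_weight))
        d$pas_off[nrow(d)] <- -(t_off + len - 1L)  # marker; resolved below
        attr(d, "spp_len") <- len
      }
      iso[[g]] <- d
    }

    # genomic isoform coordinates (strand-aware)
    iso_tab <- do.call(rbind, lapply(seq_len(n), function(g) {
      d <- iso[[g]]
      dirn <- if (plus[g]) 1L else -1L
      tss <- ann_tss[g] + dirn * d$tss_off
      pas <- ifelse(d$type == "spprna",
                    tss + dirn * (attr(d, "spp_len") - 1L),
                    ann_pas[g] - dirn * d$pas_off)
      data.frame(gene_id = genes$gene_id[g],
                 isoform_id = paste0(genes$gene_id[g], ".", seq_len(nrow(d))),
                 chrom = chrom[g], strand = if (plus[g]) "+" else "-",
                 tss = as.integer(tss), pas = as.integer(pas),
                 weight = d$weight, type = d$type)
    }))

    expr <- stats::rgamma(n, shape = 2, rate = 2) + 1e-6
    n_g <- as.integer(stats::rmultinom(1L, depth, expr))

    # per-molecule isoform assignment
    iso_of_gene <- split(seq_len(nrow(iso_tab)), iso_tab$gene_id)
    iso_of_gene <- iso_of_gene[genes$gene_id]
    mol_iso <- integer(depth)
    pos <- 0L
    for (g in seq_len(n)) {
      if (n_g[g] == 0L) next
      rows <- iso_of_gene[[g]]
      mol_iso[pos + seq_len(n_g[g])] <-
        rows[sample.int(length(rows), n_g[g], replace = TRUE,
                        prob = iso_tab$weight[rows])]
      pos <- pos + n_g[g]
    }
    mol_gene <- rep(seq_len(n), n_g)

    jit <- function(m, sd) {
      if (sd <= 0) return(integer(m))
      as.integer(pmax(-3 * sd, pmin(3 * sd, round(stats::rnorm(m, 0, sd)))))
    }
    five <- iso_tab$tss[mol_iso] + jit(depth, tss_dispersion)
    three <- iso_tab$pas[mol_iso] + jit(depth, pas_dispersion)

    # mispriming: only at genes with a planted tract
    tract_of <- match(genes$gene_id, sim$a_tracts$gene_id)
    mis <- stats::runif(depth) < mispriming_rate & !is.na(tract_of[mol_gene])
    if (any(mis)) {
      tr <- tract_of[mol_gene[mis]]
      mis_pas <- ifelse(plus[mol_gene[mis]],
                        start(sim$a_tracts)[tr] - 1L,
                        end(sim$a_tracts)[tr] + 1L)
      three[mis] <- mis_pas
    }
    # 3'-biased artifactual 5' ends (unsupported TSS)
    art <- stats::runif(depth) < artifact_rate & !mis
    if (any(art)) {
      g <- mol_gene[art]
      off <- 50L + floor(stats::runif(sum(art)) * 251L)  # 50..300 from gene end
      five[art] <- ifelse(plus[g], ann_pas[g] - off, ann_pas[g] + off)
    }
    # enforce end ordering after jitter
    swap <- ifelse(plus[mol_gene], five > three, three > five)
    if (any(swap)) { tmp <- five[swap]; five[swap] <- three[swap]; three[swap] <- tmp }

    pairs <- EndPairs(chrom[mol_gene], five, three,
                      ifelse(plus[mol_gene], "+", "-"))
    molecules <- data.frame(gene_id = genes$gene_id[mol_gene],
                            isoform_id = iso_tab$isoform_id[mol_iso],
                            misprimed = mis, artifact = art,
                            five = five, three = three,
                            stringsAsFactors = FALSE)
    tss_support <- GenomicRanges::reduce(
      GRanges(iso_tab$chrom, IRanges(iso_tab$tss - 20L, iso_tab$tss + 20L),
              strand = iso_tab$strand))
    list(pairs = pairs, isoforms = iso_tab, molecules = molecules,
         tss_support = tss_support,
         spprna_genes = genes$gene_id[spp_genes],
         params = list(mean_isoforms = mean_isoforms,
                       tss_dispersion = tss_dispersion,
                       pas_dispersion = pas_dispersion,
                       spprna_gene_fraction = spprna_gene_fraction,
                       spprna_length_median = spprna_length_median,
                       spprna_length_sdlog = spprna_length_sdlog,
                       spprna_weight = spprna_weight, depth = depth,
                       mispriming_rate = mispriming_rate,
                       artifact_rate = artifact_rate, seed = seed))
  })
}

#' Simulate a stranded nascent-transcription coverage track
#'
#' Poisson per-base counts at \code{body_rate} over every gene body plus a
#' 150 nt upstream extension (nascent polymerase density begins just
#' upstream of the annotated TSS, so a +/- 150 nt promoter window sees
#' uniform signal), on the gene's strand; genes in \code{spprna_genes}
#' instead emit at \code{promoter_peak_gain * body_rate} over the first
#' 150 nt downstream of the TSS (gain 1 = no peak), emulating
#' promoter-proximal RNAPII stalling.
#'
#' @param genes gene \code{GRanges}.
#' @param spprna_genes character vector of gene ids carrying a promoter
#'   peak.
#' @param promoter_peak_gain multiplicative promoter rate gain (default 10).
#' @param body_rate per-base Poisson rate over gene bodies (> 0).
#' @param seqlengths named integer vector of chromosome lengths (e.g.
#'   \code{Biostrings::width} of the simulated genome).
#' @param seed integer seed.
#' @return A list: \code{track} (\linkS4class{CoverageTrack}),
#'   \code{truth} (data.frame gene_id, gain).
#' @export
simulateCoverage <- function(genes, spprna_genes, promoter_peak_gain = 10,
                             body_rate = 1, seqlengths, seed = 1) {
  if (body_rate <= 0) stop("body_rate must be positive")
  if (promoter_peak_gain <= 0) stop("promoter_peak_gain must be positive")
  .with_seed(seed, {
    chrom <- as.character(GenomeInfoDb::seqnames(genes))
    plus <- as.character(strand(genes)) == "+"
    peak <- genes$gene_id %in% spprna_genes
    tss <- annotatedTSS(genes)
    vecs <- list(`+` = list(), `-` = list())
    for (chr in unique(chrom)) {
      for (str in c("+", "-")) {
        v <- numeric(seqlengths[[chr]])
        gi <- which(chrom == chr & (plus == (str == "+")))
        for (g in gi) {
          st <- start(genes)[g]; en <- end(genes)[g]
          if (plus[g]) st <- max(1L, st - 150L)
          else en <- min(length(v), en + 150L)
          rate <- rep(body_rate, en - st + 1L)
          if (peak[g]) {
            if (plus[g]) {
              pk <- seq.int(tss[g], min(en, tss[g] + 150L)) - st + 1L
            } else {
              pk <- seq.int(max(st, tss[g] - 150L), tss[g]) - st + 1L
            }
            rate[pk] <- promoter_peak_gain * body_rate
          }
          v[st:en] <- v[st:en] + stats::rpois(length(rate), rate)
        }
        vecs[[str]][[chr]] <- S4Vectors::Rle(v)
      }
    }
    list(track = CoverageTrack(plus = IRanges::RleList(vecs[["+"]]),
                               minus = IRanges::RleList(vecs[["-"]])),
         truth = data.frame(gene_id = genes$gene_id,
                            gain = ifelse(peak, promoter_peak_gain, 1)))
  })
}

#' Score recovered clusters against simulation truth
#'
#' A final cluster matches a true isoform when, on the same chromosome and
#' strand, both its representative TSS and PAS lie within \code{tol} nt of
#' the isoform's true ends. Precision is the matched fraction of clusters;
#' recall is the matched fraction of discoverable isoforms (those with at
#' least \code{min_support} clean -- non-misprimed, non-artifact --
#' molecules).
#'
#' @param clusters final \linkS4class{TIFClusters}.
#' @param truth result of [simulateEndPairs()].
#' @param tol matching tolerance in nt (default 20, the merge window).
#' @param min_support discoverability threshold (default 3).
#' @return A list: \code{precision}, \code{recall}, \code{n_clusters},
#'   \code{n_discoverable}.
#' @export
clusterRecovery <- function(clusters, truth, tol = 20, min_support = 3) {
  iso <- truth$isoforms
  mol <- truth$molecules
  clean <- table(mol$isoform_id[!mol$misprimed & !mol$artifact])
  disc <- iso[iso$isoform_id %in% names(clean)[clean >= min_support], ]
  key_c <- paste(as.character(GenomeInfoDb::seqnames(clusters)),
                 as.character(strand(clusters)))
  key_t <- paste(disc$chrom, disc$strand)
  ctss <- fivePrime(clusters); cpas <- threePrime(clusters)
  matched_c <- logical(length(clusters))
  matched_t <- logical(nrow(disc))
  for (k in unique(key_t)) {
    ti <- which(key_t == k); ci <- which(key_c == k)
    if (length(ci) == 0L) next
    for (t in ti) {
      hit <- ci[abs(ctss[ci] - disc$tss[t]) <= tol &
                  abs(cpas[ci] - disc$pas[t]) <= tol]
      if (length(hit)) { matched_t[t] <- TRUE; matched_c[hit] <- TRUE }
    }
  }
  list(precision = if (length(clusters)) mean(matched_c) else NA_real_,
       recall = if (nrow(disc)) mean(matched_t) else NA_real_,
       n_clusters = length(clusters), n_discoverable = nrow(disc))
}

#' Write a simulation scenario to disk as standard formats
#'
#' Emits genome.fa, genes.gff3, pairs.bedpe, tss_support.bed and (when
#' coverage is supplied) coverage_plus/minus.bedgraph, plus truth TSVs.
#'
#' @param sim result of [simulateGenome()].
#' @param pairs result of [simulateEndPairs()].
#' @param dir output directory (created).
#' @param coverage optional result of [simulateCoverage()].
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, pairs, dir, coverage = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  g <- sim$genes
  gff <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(g)),
                    src = "tifiso", type = "gene", start = start(g),
                    end = end(g), score = ".",
                    strand = as.character(strand(g)), phase = ".",
                    attr = paste0("ID=", g$gene_id))
  writeLines(c("##gff-version 3",
               do.call(paste, c(gff, sep = "\t"))),
             file.path(dir, "genes.gff3"))
  ep <- pairs$pairs
  s <- as.character(strand(ep))
  five <- fivePrime(ep); three <- threePrime(ep)
  bedpe <- data.frame(c1 = as.character(GenomeInfoDb::seqnames(ep)),
                      s1 = five - 1L, e1 = five,
                      c2 = as.character(GenomeInfoDb::seqnames(ep)),
                      s2 = three - 1L, e2 = three,
                      name = paste0("mol", seq_along(ep)), score = 0L,
                      strand1 = s, strand2 = s)
  utils::write.table(bedpe, file.path(dir, "pairs.bedpe"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  rtracklayer::export(pairs$tss_support, file.path(dir, "tss_support.bed"),
                      format = "BED")
  utils::write.table(pairs$isoforms, file.path(dir, "truth_isoforms.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairs$molecules, file.path(dir, "truth_molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage)) {
    .write_bedgraph <- function(rl, path) {
      grl <- methods::as(rl, "GRanges")
      grl <- grl[grl$score > 0]
      rtracklayer::export(grl, path, format = "bedGraph")
    }
    .write_bedgraph(coverage$track@plus, file.path(dir, "coverage_plus.bedgraph"))
    .write_bedgraph(coverage$track@minus, file.path(dir, "coverage_minus.bedgraph"))
  }
  invisible(dir)
}
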