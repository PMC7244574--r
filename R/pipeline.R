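#' Run the full analysis pipeline and collect a machine-readable report
#'
#' Wires the stages in order: (optional) simulation -> end-pair clustering
#' (pre-cluster, merge, support / mispriming / TSS-support filters) ->
#' gene assignment and isoform classification -> sppRNA calling ->
#' (optional) nascent pausing metrics -> (optional) promoter motif
#' densities. Every parameter and seed used is echoed into the report;
#' rerunning with the same config reproduces the report exactly.
#'
#' @param config a list. Either \code{simulate = list(...)} (arguments for
#'   [simulateGenome()] / [simulateEndPairs()] / [simulateCoverage()]) or
#'   file paths \code{genome} (FASTA), \code{genes} (GFF3/BED), \code{pairs}
#'   (BEDPE), \code{tss_support} (BED), and optionally
#'   \code{coverage_plus} / \code{coverage_minus} (bedGraph). Optional
#'   elements: \code{params} (a \linkS4class{PipelineParams}),
#'   \code{motifs} (character IUPAC patterns; default GAGAR and RGCCCAW),
#'   \code{seed}.
#' @return A list with elements \code{counts} (per-stage cluster counts),
#'   \code{category_proportions}, \code{isoforms_per_gene_mean},
#'   \code{n_expressed_genes}, \code{spprna} (fraction, median width,
#'   n_calls), \code{pausing} (summary, when coverage present),
#'   \code{motif_density} (per pattern mean density), \code{params},
#'   \code{objects} (clusters, calls, ... for downstream use).
#' @export
runPipeline <- function(config) {
  params <- config$params
  if (is.null(params)) params <- PipelineParams()
  seed <- if (!is.null(config$seed)) config$seed else params@random_seed
  validObject(params)

  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    sim <- do.call(simulateGenome, c(
      simargs[intersect(names(simargs),
                        names(formals(simulateGenome)))],
      if (!"seed" %in% names(simargs)) list(seed = seed)))
    ep <- do.call(simulateEndPairs, c(list(sim = sim),
      simargs[intersect(names(simargs), names(formals(simulateEndPairs))[-1])],
      if (!"seed" %in% names(simargs)) list(seed = seed)))
    genome <- sim$genome
    genes <- sim$genes
    pairs <- ep$pairs
    tss_support <- ep$tss_support
    cov <- NULL
    if (isTRUE(simargs$coverage)) {
      cv <- simulateCoverage(genes, ep$spprna_genes,
                             seqlengths = stats::setNames(
                               Biostrings::width(genome), names(genome)),
                             seed = seed)
      cov <- cv$track
    }
    truth <- ep
  } else {
    for (f in c("genome", "genes", "pairs", "tss_support"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing input file for '", f, "'")
    genome <- Biostrings::readDNAStringSet(config$genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
    genes <- readGeneAnnotation(config$genes)
    pairs <- readEndPairs(config$pairs)
    tss_support <- readTSSSupport(config$tss_support)
    cov <- NULL
    if (!is.null(config$coverage_plus))
      cov <- CoverageTrack(plus = readCoverage(config$coverage_plus),
                           minus = if (!is.null(config$coverage_minus))
                             readCoverage(config$coverage_minus)
                           else IRanges::RleList())
    truth <- NULL
  }

  run <- runClusterPipeline(pairs, genome, tss_support, params)
  clusters <- classifyClusters(
    assignClustersToGenes(run$clusters, genes), genes,
    tau = params@category_tolerance)
  ipg <- isoformsPerGene(clusters, genes)
  cats <- categorySummary(clusters)
  calls <- callSppRNA(clusters, genes, params@spprna_max_len,
                      params@tss_flank)
  spp <- if (nrow(ipg$per_gene))
    sppRNAGeneStats(calls, ipg$per_gene$gene_id)
  else list(fraction = NA_real_, median_width = NA_real_)

  pausing <- NULL
  if (!is.null(cov)) {
    pidx <- pausingIndex(cov, genes, params@pi_promoter_halfwidth,
                         params@pi_body_shrink, params@pi_min_gene_len,
                         params@pi_expr_fraction)
    ok <- pidx$pausing_index[pidx$eligible]
    pausing <- list(n_genes = sum(pidx$eligible),
                    median = stats::median(ok), mean = mean(ok))
  }

  motif_density <- NULL
  patterns <- if (!is.null(config$motifs)) config$motifs
    else c("GAGAR", "RGCCCAW")
  if (length(patterns)) {
    win <- motifWindowPreset("heatmap")
    spp_g <- genes[genes$gene_id %in% S4Vectors::mcols(calls)$gene_id]
    if (length(spp_g)) {
      w <- extractPromoterWindows(genome, spp_g, win["upstream"],
                                  win["downstream"])
      motif_density <- lapply(stats::setNames(patterns, patterns), function(p)
        mean(motifDensity(w, p)$density))
    }
  }

  list(counts = run$counts,
       category_proportions = stats::setNames(cats$prop_a, cats$category),
       isoforms_per_gene_mean = ipg$mean,
       n_expressed_genes = nrow(ipg$per_gene),
       spprna = list(fraction = spp$fraction,
                     median_width = spp$median_width,
                     n_calls = length(calls)),
       pausing = pausing,
       motif_density = motif_density,
       params = c(stats::setNames(
         lapply(slotNames(params), function(s) slot(params, s)),
         slotNames(params)), list(seed = seed)),
       objects = list(clusters = clusters, calls = calls, truth = truth,
                      genes = genes, coverage = cov))
}
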