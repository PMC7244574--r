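# Independent re-evaluation of the category rule table for one cluster.
oracle_category <- function(tss, pas, strand, gene, tau) {
  if (is.na(gene$gene_id)) return("intergenic")
  if (gene$antisense) return("antisense")
  if (strand == "+") {
    dT <- tss - gene$start; dP <- gene$end - pas
  } else {
    dT <- gene$end - tss; dP <- pas - gene$start
  }
  if (dT > tau && dP <= tau) return("internal_initiation")
  if (dP > tau && dT <= tau) return("internal_termination")
  if (dT > tau && dP > tau) return("internal_both")
  if (dT < -tau && abs(dP) <= tau) return("five_prime_extended")
  if (dP < -tau && abs(dT) <= tau) return("three_prime_extended")
  "full_span"
}

test_that("cluster-gene assignment prefers sense maximal overlap", {
  genes <- toy_genes(4)  # g1 +, g2 -, g3 +, g4 -
  # fully inside g1, same strand
  cl <- TIFClusters("chr1", start(genes)[1] + 10L, end(genes)[1] - 10L,
                    "+", 3L)
  a <- assignClustersToGenes(cl, genes)
  expect_equal(S4Vectors::mcols(a)$gene_id, "g1")
  expect_false(S4Vectors::mcols(a)$antisense)
  # inside g2 but on the + strand: antisense assignment
  cl2 <- TIFClusters("chr1", start(genes)[2] + 10L, end(genes)[2] - 10L,
                     "+", 3L)
  a2 <- assignClustersToGenes(cl2, genes)
  expect_equal(S4Vectors::mcols(a2)$gene_id, "g2")
  expect_true(S4Vectors::mcols(a2)$antisense)
  # in the intergenic gap: no assignment
  cl3 <- TIFClusters("chr1", 10L, 100L, "+", 3L)
  expect_true(is.na(S4Vectors::mcols(assignClustersToGenes(cl3, genes))$gene_id))
  # clusters over flagged (overlapping) genes are excluded territory
  genes$overlapsOtherGene[1] <- TRUE
  a4 <- assignClustersToGenes(cl, genes)
  expect_true(is.na(S4Vectors::mcols(a4)$gene_id))
})

test_that("category rule table matches an independent oracle on random input", {
  genes <- toy_genes(6, len = 2000, gap = 1000)
  withr::with_seed(42, {
    for (rep in 1:3) {
      n <- 120
      g <- sample(6, n, replace = TRUE)
      tss <- start(genes)[g] + sample(-600:1500, n, replace = TRUE)
      len <- sample(50:2600, n, replace = TRUE)
      pas <- tss + len
      strand <- sample(c("+", "-"), n, replace = TRUE)
      cl <- TIFClusters("chr1", ifelse(strand == "+", tss, pas),
                        ifelse(strand == "+", pas, tss), strand,
                        rep(3L, n))
      out <- classifyClusters(cl, genes, tau = 100)
      got <- as.character(S4Vectors::mcols(out)$category)
      ids <- S4Vectors::mcols(out)$gene_id
      anti <- S4Vectors::mcols(out)$antisense
      want <- vapply(seq_len(n), function(i) {
        gi <- match(ids[i], genes$gene_id)
        oracle_category(fivePrime(out)[i], threePrime(out)[i], strand[i],
                        list(gene_id = ids[i], antisense = anti[i],
                             start = start(genes)[gi], end = end(genes)[gi]),
                        tau = 100)
      }, character(1))
      expect_equal(got, want)
      # partition: every cluster gets exactly one category
      expect_false(anyNA(got))
      expect_equal(sum(table(S4Vectors::mcols(out)$category)), n)
    }
  })
})

test_that("exact-boundary clusters are full span and tau -> 0 keeps them so", {
  genes <- toy_genes(2)
  cl <- TIFClusters("chr1", annotatedTSS(genes), annotatedPAS(genes),
                    as.character(strand(genes)), c(3L, 3L))
  for (tau in c(100, 1, 1e-9)) {
    out <- classifyClusters(cl, genes, tau = tau)
    expect_equal(as.character(S4Vectors::mcols(out)$category),
                 rep("full_span", 2), info = paste("tau =", tau))
  }
  expect_error(classifyClusters(cl, genes, tau = 0), "tau")
  # TSS at the gene midpoint, PAS at the annotated PAS: internal initiation
  mid <- TIFClusters("chr1", start(genes)[1] + 500L, end(genes)[1], "+", 3L)
  expect_equal(as.character(S4Vectors::mcols(
    classifyClusters(mid, genes))$category), "internal_initiation")
})

test_that("classification is invariant to gene and cluster ordering", {
  genes <- toy_genes(6, len = 2000, gap = 1000)
  withr::with_seed(8, {
    n <- 60
    g <- sample(6, n, replace = TRUE)
    tss <- start(genes)[g] + sample(0:1200, n, replace = TRUE)
    cl <- TIFClusters("chr1", tss, tss + 700L, rep("+", n), rep(3L, n))
    ref <- classifyClusters(cl, genes)
    perm_g <- sample(length(genes))
    perm_c <- sample(n)
    alt <- classifyClusters(cl[perm_c], genes[perm_g])
    expect_equal(as.character(S4Vectors::mcols(alt)$category)[order(perm_c)],
                 as.character(S4Vectors::mcols(ref)$category))
  })
})

test_that("boundary distance table matches hand computation", {
  genes <- toy_genes(2, len = 1000, gap = 500)  # g1 + at 501-1500, g2 - at 2001-3000
  cl <- TIFClusters("chr1",
                    tss = c(501, 1001, 401, 2900, 3000, 2500),
                    pas = c(1500, 1500, 1500, 2101, 2001, 2101),
                    strand = c("+", "+", "+", "-", "-", "-"),
                    support = rep(3L, 6))
  d <- boundaryDistanceTable(cl, genes)
  # hand-worked: signed interior distances over gene length 1000
  expect_equal(d$d_tss_norm, c(0, 0.5, -0.1, 0.1, 0, 0.5))
  expect_equal(d$d_pas_norm, c(0, 0, 0, 0.1, 0, 0.1))
  expect_error(boundaryDistanceTable(cl, {
    g <- genes; IRanges::ranges(g)[1] <- IRanges::IRanges(501, 501)
    g  # degenerate gene length guards
  }), NA)  # width-1 gene is still positive length
})

test_that("isoforms per expressed gene averages distinct clusters", {
  genes <- toy_genes(3)
  cl <- TIFClusters("chr1",
                    tss = c(start(genes)[1], start(genes)[1] + 300,
                            end(genes)[2]),
                    pas = c(end(genes)[1], end(genes)[1],
                            start(genes)[2]),
                    strand = c("+", "+", "-"), support = rep(3L, 3))
  ipg <- isoformsPerGene(cl, genes)
  expect_equal(nrow(ipg$per_gene), 2L)   # g3 has no cluster: not expressed
  expect_equal(sort(ipg$per_gene$n_isoforms), c(1L, 2L))
  expect_equal(ipg$mean, 1.5)
  empty <- isoformsPerGene(TIFClusters(), genes)
  expect_true(is.na(empty$mean))
})

test_that("isoform-count recovery approaches the zero-truncated Poisson truth", {
  # deep coverage, no sppRNAs: the estimator sees the ZTP isoform counts
  sim <- simulateGenome(n_genes = 120, seed = 31)
  ep <- simulateEndPairs(sim, depth = 120 * 600, spprna_gene_fraction = 0,
                         mispriming_rate = 0, artifact_rate = 0, seed = 31)
  run <- runClusterPipeline(ep$pairs, sim$genome, ep$tss_support)
  ipg <- isoformsPerGene(assignClustersToGenes(run$clusters, sim$genes),
                         sim$genes)
  truth_mean <- mean(table(ep$isoforms$gene_id))
  expect_lt(abs(ipg$mean - truth_mean), 0.3)
})

test_that("category summary counts proportions and guards zero categories", {
  genes <- toy_genes(2)
  mk <- function(n_full, n_int) {
    tss <- c(rep(start(genes)[1], n_full + n_int))
    pas <- rep(end(genes)[1], n_full + n_int)
    tss[seq_len(n_int)] <- start(genes)[1] + 400L
    classifyClusters(TIFClusters("chr1", tss, pas,
                                 rep("+", n_full + n_int),
                                 rep(3L, n_full + n_int)), genes)
  }
  a <- mk(6, 4)
  s <- categorySummary(a)
  expect_equal(s$prop_a[s$category == "full_span"], 0.6)
  expect_equal(s$prop_a[s$category == "internal_initiation"], 0.4)
  expect_equal(sum(s$prop_a), 1)
  # identical sets give log2FC 0 everywhere a category is populated
  s2 <- categorySummary(a, a)
  expect_true(all(s2$log2fc == 0))
  # a category present in b but absent in a uses the half-minimum pseudo-prop
  b <- mk(10, 0)
  s3 <- categorySummary(b, a)
  expect_equal(s3$log2fc[s3$category == "internal_initiation"],
               log2(0.4 / (0.5 / length(b))))
})

test_that("size distribution uses a strict width bound and order statistics", {
  cl <- TIFClusters("chr1", rep(1L, 3), c(90L, 93L, 100L), rep("+", 3),
                    rep(3L, 3))
  expect_equal(sizeDistribution(cl)$median, 93)  # widths 90, 93, 100
  big <- TIFClusters("chr1", c(1L, 1L), c(6000L, 5999L), c("+", "+"),
                     c(3L, 3L))
  sd1 <- sizeDistribution(big)      # widths 6000 (excluded), 5999 (kept)
  expect_equal(sd1$n, 1L)
  expect_equal(sd1$widths, 5999L)
  withr::with_seed(19, {
    w <- sample(50:5999, 1000, replace = TRUE)
    cl <- TIFClusters("chr1", rep(1L, 1000), w, rep("+", 1000),
                      rep(3L, 1000))
    s <- sizeDistribution(cl)
    srt <- sort(w)  # widths equal pas with tss = 1
    expect_equal(s$median, (srt[500] + srt[501]) / 2)
    expect_equal(s$q1, unname(stats::quantile(w, 0.25)))
    expect_equal(s$q3, unname(stats::quantile(w, 0.75)))
  })
})
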