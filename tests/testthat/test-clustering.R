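test_that("pre-clustering counts multiplicities of exact end-pairs", {
  ep <- EndPairs("chr1", c(100, 100, 100), c(600, 600, 601), rep("+", 3))
  pc <- buildPreclusters(ep)
  expect_equal(length(pc), 2L)
  expect_equal(clusterSupport(pc), c(2L, 1L))  # exact both-end match only

  withr::with_seed(5, {
    five <- sample(1:50, 50, replace = TRUE)
    three <- five + sample(1:30, 50, replace = TRUE)
    ep <- EndPairs("chr1", five, three, rep("+", 50))
    pc <- buildPreclusters(ep)
    # counting oracle: multiset of distinct pairs with multiplicities
    key <- paste(five, three)
    expect_equal(length(pc), length(unique(key)))
    expect_equal(sum(clusterSupport(pc)), 50L)
    expect_equal(sort(clusterSupport(pc)), sort(as.integer(table(key))))
  })
  expect_equal(length(buildPreclusters(EndPairs())), 0L)
})

test_that("merge window is strict and support-weighted representatives win", {
  # 19 nt apart at both ends -> merge; dominant member's ends represent
  pc <- TIFClusters("chr1", c(100, 119), c(500, 519), c("+", "+"), c(2L, 1L))
  m <- mergePreclusters(pc, 20)
  expect_equal(length(m), 1L)
  expect_equal(clusterSupport(m), 3L)
  expect_equal(fivePrime(m), 100L)
  expect_equal(threePrime(m), 500L)

  # distance exactly 20 does not merge
  pc2 <- TIFClusters("chr1", c(100, 120), c(500, 500), c("+", "+"), c(1L, 1L))
  expect_equal(length(mergePreclusters(pc2, 20)), 2L)

  # chained merging: A-B and B-C link, so A-C joins transitively
  pc3 <- TIFClusters("chr1", c(100, 115, 130), c(500, 515, 530),
                     rep("+", 3), rep(1L, 3))
  expect_equal(length(mergePreclusters(pc3, 20)), 1L)

  # support ties break to the outermost position (5'-most TSS on +)
  pc4 <- TIFClusters("chr1", c(100, 110), c(500, 510), c("+", "+"), c(1L, 1L))
  m4 <- mergePreclusters(pc4, 20)
  expect_equal(fivePrime(m4), 100L)
  expect_equal(threePrime(m4), 510L)
  # and mirrored on the minus strand (5'-most = rightmost)
  pc5 <- TIFClusters("chr1", c(510, 500), c(110, 100), c("-", "-"), c(1L, 1L))
  m5 <- mergePreclusters(pc5, 20)
  expect_equal(fivePrime(m5), 510L)
  expect_equal(threePrime(m5), 100L)
})

test_that("merge partition equals the brute-force transitive-closure oracle", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      n <- sample(10:120, 1)
      five <- sample(1:800, n, replace = TRUE)
      three <- five + sample(40:400, n, replace = TRUE)
      key <- !duplicated(paste(five, three))
      five <- five[key]; three <- three[key]
      supp <- sample(1:4, length(five), replace = TRUE)
      pc <- TIFClusters("chr1", five, three, rep("+", length(five)), supp)
      m <- mergePreclusters(pc, 20, keepMembers = TRUE)
      # rebuild the implementation's partition over the input preclusters
      labels <- integer(length(five))
      mem <- S4Vectors::mcols(m)$members
      for (ci in seq_along(mem)) {
        idx <- match(paste(mem[[ci]]$five, mem[[ci]]$three),
                     paste(five, three))
        labels[idx] <- ci
      }
      oracle <- oracle_merge_partition(five, three, 20)
      expect_equal(canonical_partition(labels), canonical_partition(oracle))
      # support conservation within the same instance
      expect_equal(sum(clusterSupport(m)), sum(supp))
    }
  })
})

test_that("merging is order independent and monotone in its parameters", {
  withr::with_seed(77, {
    five <- sample(1:2000, 150, replace = TRUE)
    three <- five + sample(30:300, 150, replace = TRUE)
    ep <- EndPairs("chr1", five, three, rep("+", 150))
    perm <- sample(length(ep))
    m1 <- mergePreclusters(buildPreclusters(ep), 20)
    m2 <- mergePreclusters(buildPreclusters(ep[perm]), 20)
    expect_equal(fivePrime(m1), fivePrime(m2))
    expect_equal(threePrime(m1), threePrime(m2))
    expect_equal(clusterSupport(m1), clusterSupport(m2))
    # widening the window never increases the cluster count
    counts <- vapply(c(5, 10, 20, 40, 80), function(w)
      length(mergePreclusters(buildPreclusters(ep), w)), 1L)
    expect_true(all(diff(counts) <= 0))
    # raising min_support never increases the kept count
    kept <- vapply(1:6, function(ms) length(filterSupport(m1, ms)), 1L)
    expect_true(all(diff(kept) <= 0))
  })
})

test_that("support filter keeps >= 3 and discards 2 at the default", {
  cl <- TIFClusters("chr1", c(100, 300, 500), c(200, 400, 600),
                    rep("+", 3), c(3L, 2L, 1L))
  kept <- filterSupport(cl)
  expect_equal(clusterSupport(kept), 3L)
  expect_equal(attr(kept, "discarded"), 2L)
  expect_equal(length(filterSupport(TIFClusters("chr1", 1, 10, "+", 1L))), 0L)
  expect_error(filterSupport(cl, 0), "min_support")
})

test_that("mispriming filter detects A-runs around the PAS, strand-aware", {
  base <- strrep("C", 300)
  # plant AAAAAA right after a + strand PAS at 100
  s <- paste0(substr(base, 1, 100), "AAAAAA", substr(base, 107, 300))
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  plus_hit <- TIFClusters("chr1", 20, 100, "+", 3L)
  expect_equal(length(filterMispriming(plus_hit, genome)), 0L)
  # run of only 5 A's is below threshold
  s5 <- paste0(substr(base, 1, 100), "AAAAA", substr(base, 106, 300))
  g5 <- Biostrings::DNAStringSet(s5); names(g5) <- "chr1"
  expect_equal(length(filterMispriming(plus_hit, g5)), 1L)
  # minus-strand cluster: TTTTTT on the forward reference near its PAS
  st <- paste0(substr(base, 1, 197), "TTTTTT", substr(base, 204, 300))
  gt <- Biostrings::DNAStringSet(st); names(gt) <- "chr1"
  minus_hit <- TIFClusters("chr1", 280, 200, "-", 3L)
  expect_equal(length(filterMispriming(minus_hit, gt)), 0L)
  # the same T-run does not discard a + strand cluster
  plus_there <- TIFClusters("chr1", 100, 200, "+", 3L)
  expect_equal(length(filterMispriming(plus_there, gt)), 1L)
  # window truncation at the chromosome edge is not an error
  edge <- TIFClusters("chr1", 1, 3, "+", 3L)
  expect_equal(length(filterMispriming(edge, gt)), 1L)
})

test_that("TSS-support filter is boundary inclusive and matches brute force", {
  sup <- GRanges("chr1", IRanges(100, 120), strand = "+")
  inside <- TIFClusters("chr1", 110, 400, "+", 3L)
  expect_equal(length(filterTSSSupport(inside, sup)), 1L)
  # 10 nt outside the interval with flank 10 -> still kept (inclusive)
  at_flank <- TIFClusters("chr1", 90, 400, "+", 3L)
  expect_equal(length(filterTSSSupport(at_flank, sup, 10)), 1L)
  beyond <- TIFClusters("chr1", 89, 400, "+", 3L)
  expect_equal(length(filterTSSSupport(beyond, sup, 10)), 0L)
  # same position on the wrong strand is not support
  wrong_strand <- TIFClusters("chr1", 110, 50, "-", 3L)
  expect_equal(length(filterTSSSupport(wrong_strand, sup)), 0L)

  withr::with_seed(23, {
    tss <- sample(1:2000, 80, replace = TRUE)
    cl <- TIFClusters("chr1", tss, tss + 500L, rep("+", 80),
                      rep(3L, 80))
    st <- sample(1:2000, 15)
    sup <- GRanges("chr1", IRanges(st, st + sample(5:40, 15, replace = TRUE)),
                   strand = "+")
    kept <- filterTSSSupport(cl, sup, 10)
    # brute-force all-pairs containment with the flank applied
    expected <- vapply(tss, function(p)
      any(p >= start(sup) - 10 & p <= end(sup) + 10), logical(1))
    expect_equal(fivePrime(kept), tss[expected])
  })
})

test_that("an empty TSS-support set removes everything with a warning", {
  cl <- TIFClusters("chr1", 100, 400, "+", 3L)
  expect_warning(res <- filterTSSSupport(cl, GRanges()), "empty")
  expect_equal(length(res), 0L)
})

test_that("pipeline composes stages in order with conserved counts", {
  expect_equal(runClusterPipeline(EndPairs(), toy_genome(100),
                                  GRanges())$counts[["preclusters"]], 0L)
  # no-noise scenario on an A/T-free genome: the mispriming and TSS-support
  # filters are provably no-ops, so final = merged clusters with support >= 3
  withr::with_seed(9, {
    g <- Biostrings::DNAStringSet(paste(
      sample(c("C", "G"), 5000, replace = TRUE), collapse = ""))
    names(g) <- "chr1"
    five <- rep(c(100L, 800L, 2000L), times = c(4, 3, 2))
    three <- rep(c(700L, 1400L, 2600L), times = c(4, 3, 2))
    ep <- EndPairs("chr1", five, three, rep("+", 9))
    sup <- GRanges("chr1", IRanges(c(95, 795, 1995), width = 11),
                   strand = "+")
    run <- runClusterPipeline(ep, g, sup)
    expect_true(all(diff(run$counts[-1]) <= 0))
    byhand <- filterSupport(mergePreclusters(buildPreclusters(ep), 20), 3)
    expect_equal(fivePrime(run$clusters), fivePrime(byhand))
    expect_equal(clusterSupport(run$clusters), clusterSupport(byhand))
    expect_equal(unname(run$counts),
                 c(9L, 3L, 3L, 2L, 2L, 2L))
  })
})
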