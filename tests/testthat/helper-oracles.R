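suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(withr)
})

# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately use naive algorithms (all-pairs
# scans, per-base loops, full enumeration) independent of the package code
# paths they check.

# All-pairs single-linkage components under |d5| < w AND |d3| < w,
# via breadth-first search over the full adjacency matrix.
oracle_merge_partition <- function(five, three, w) {
  n <- length(five)
  if (n == 0L) return(integer(0))
  adj <- abs(outer(five, five, "-")) < w & abs(outer(three, three, "-")) < w
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    nxt <- nxt + 1L
    queue <- i
    comp[i] <- nxt
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  comp
}

# Canonical form of a partition: list of sorted member index vectors,
# ordered by smallest member.
canonical_partition <- function(labels) {
  grp <- unname(lapply(split(seq_along(labels), labels), sort))
  grp[order(vapply(grp, min, 1L))]
}

# Character-class regex oracle for IUPAC motif scanning (N matches nothing).
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste0(vapply(strsplit(pattern, "")[[1]], function(ch) {
    set <- strsplit(map[[ch]], "")[[1]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

oracle_scan <- function(seq, pattern) {
  # zero-width lookahead reports overlapping matches; N falls in no class
  hits <- gregexpr(paste0("(?=", iupac_regex(pattern), ")"), seq,
                   perl = TRUE)[[1]]
  if (length(hits) == 1L && hits == -1L) return(integer(0))
  as.integer(hits)
}

# Exact two-sided rank-sum p-value by full enumeration of group labellings.
oracle_wilcox_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  stats <- apply(combs, 2L, function(i) sum(r[i]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# A deterministic toy annotation: n disjoint alternating-strand genes of
# length len on one chromosome.
toy_genes <- function(n = 5, len = 1000, gap = 500, chrom = "chr1") {
  starts <- gap + (seq_len(n) - 1L) * (len + gap) + 1L
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(starts, starts + len - 1L),
                               strand = rep(c("+", "-"), length.out = n))
  gr$gene_id <- paste0("g", seq_len(n))
  gr$overlapsOtherGene <- rep(FALSE, n)
  gr
}

# Random DNAStringSet genome with one chromosome of given length.
toy_genome <- function(len = 10000, chrom = "chr1", seed = 1) {
  withr::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    g <- Biostrings::DNAStringSet(s)
    names(g) <- chrom
    g
  })
}

# Uniform-value coverage track over one chromosome.
uniform_track <- function(len = 10000, value = 1, chrom = "chr1") {
  rl <- IRanges::RleList(S4Vectors::Rle(value, len))
  names(rl) <- chrom
  tifiso::CoverageTrack(plus = rl, minus = rl)
}
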