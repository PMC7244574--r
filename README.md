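# tifiso

Transcript isoform sequencing (TIF-seq) reads out the capped 5′ end (TSS)
and the polyadenylation site (PAS) of the *same* RNA molecule, so every
sequenced molecule is a genomic end-pair. `tifiso` turns aligned,
deduplicated end-pairs into transcript-isoform calls and the downstream
genome-wide analyses built on them:

- **TIF-cluster calling** — end-pairs overlapping exactly at both ends are
  collapsed into pre-clusters; pre-clusters are merged by single-linkage
  transitive closure whenever *both* the TSS and the PAS distance is
  strictly below 20 nt; merged clusters are kept with ≥ 3 supporting read
  pairs, purged of oligo(dT) mispriming artifacts (a genomic A-run of ≥ 6 nt
  within ±10 nt of the PAS on the sense strand), and required to have a TSS
  inside an independent TSS-seq support interval.
- **Isoform classification** — each final cluster is assigned to the
  non-overlapping gene it best matches and labelled with one of eight
  categories (full span, internal initiation / termination / both, 5′/3′
  extended, antisense, intergenic) using an explicit boundary tolerance
  τ (100 nt by default); summaries include gene-length-normalised boundary
  distance tables, isoforms per expressed gene, category proportions with
  cross-genotype log2 fold-changes, and width distributions (< 6,000 nt).
- **sppRNA calling** — short promoter-proximal RNAs: clusters < 350 nt wide
  whose TSS falls within ±40 nt of an annotated gene TSS and whose span
  overlaps no annotated termination site.
- **Promoter-proximal stalling metrics** — from stranded nascent-
  transcription coverage (e.g. pNET-seq): gene-body signal over genes
  shrunk 200 nt at each boundary, the 5′ pausing index
  PI = TPM(TSS ± 150 nt) / TPM(gene shrunk 300 nt) for non-overlapping
  genes > 1,000 nt in the top 75% by expression, quantile-bin
  expression-matched control gene sets, metagene profiles with 95%
  confidence bands, and two-sided Wilcoxon rank-sum comparisons.
- **Promoter motif scanning** — IUPAC patterns (GAGA-box `GAGAR`,
  TCP-binding `RGCCCAW`/`HTGGGCY`) over strand-oriented TSS-anchored
  windows, giving per-position frequency profiles and per-window densities.
- **A ground-truth simulator** — toy genomes with planted A-tracts,
  zero-truncated-Poisson isoform counts per gene, an sppRNA subpopulation
  with a lognormal length model, end-jitter, mispriming and artifact reads,
  and Poisson coverage tracks with promoter peaks, so every stage can be
  tested against known truth without downloads.

The package is Bioconductor-style: `GRanges`-backed S4 classes
(`EndPairs`, `TIFClusters`, `CoverageTrack`), `Biostrings` genomes, and
`rtracklayer` I/O for GFF3/BED/bedGraph (BEDPE via a built-in reader).

## Worked example

```r
library(tifiso)

sim <- simulateGenome(n_genes = 200, seed = 7)
ep  <- simulateEndPairs(sim, depth = 20000, seed = 7)

run <- runClusterPipeline(ep$pairs, sim$genome, ep$tss_support)
run$counts
#>               pairs         preclusters              merged
#>               20000               18625                1495
#>    support_filtered mispriming_filtered        tss_filtered
#>                 884                 753                 733

cl  <- classifyClusters(assignClustersToGenes(run$clusters, sim$genes),
                        sim$genes)
ipg <- isoformsPerGene(cl, sim$genes)
ipg$mean
#> [1] 3.683417

calls <- callSppRNA(cl, sim$genes)
sppRNAGeneStats(calls, ipg$per_gene$gene_id)[c("fraction", "median_width")]
#> $fraction
#> [1] 0.1407035
#> $median_width
#> [1] 97

clusterRecovery(run$clusters, ep)[c("precision", "recall")]
#> $precision
#> [1] 0.9986357
#> $recall
#> [1] 0.9891892
```

Reading the numbers: 20,000 simulated molecules collapse to 733 final
TIF-clusters after merging and the three filters; expressed genes carry
~3.7 distinct isoforms each at this coverage; 14.1% of expressed genes
yield an sppRNA call with a median width of 97 nt (the simulated length
model has a 93 nt median); and 99.9% of called clusters match a true
isoform while 98.9% of sufficiently covered true isoforms are recovered.

A command-line wrapper for the same steps ships in
`inst/scripts/tifiso.R` (subcommands `simulate`, `cluster`, `classify`,
`spprna`, `run-all`).

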