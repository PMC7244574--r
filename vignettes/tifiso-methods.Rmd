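---
title: "Calling transcript isoforms and promoter-proximal RNAs from paired-end data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling transcript isoforms and promoter-proximal RNAs from paired-end data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tifiso)
```

## The measurement and its unit of analysis

TIF-seq-style libraries capture the capped 5′ end and the poly(A)
junction of the same RNA molecule, so after alignment and deduplication
each molecule reduces to an end-pair: (chromosome, strand, TSS position,
PAS position). The unit of analysis downstream is the **TIF-cluster**: a
group of end-pairs that agree, within a small window, at *both* ends. A
TIF-cluster is this method's operational definition of a transcript
isoform; isoform diversity that arises in the interior of transcripts
(alternative splicing) is invisible to it by construction.

`tifiso` represents end-pairs and clusters as `GRanges`-backed S4 objects
(`EndPairs`, `TIFClusters`) and keeps all internal coordinates 1-based
inclusive — the Bioconductor convention — converting BED-family formats
(0-based half-open) at the I/O boundary only. One convention everywhere
avoids off-by-one drift between modules.

## Clustering model

Clustering proceeds in two stages. **Pre-clustering** collapses exact
duplicates of both ends; support is the molecule multiplicity.
**Merging** joins pre-clusters under the relation
|ΔTSS| < *w* AND |ΔPAS| < *w*, with *w* = 20 nt and strict inequality
(19 merges, 20 does not). We compute the *transitive closure* of this
relation (single linkage) rather than sequentially absorbing
pre-clusters into growing clusters: sequential absorption is input-order
dependent, while the closure is deterministic, order independent, and
agrees with sequential merging in every unambiguous case. The closure is
computed per chromosome and strand by a union-find over candidate links
enumerated within a sliding 5′-sorted window (an Rcpp kernel; work is
bounded by window occupancy rather than *n*²).

A merged cluster's representative TSS (and, independently, PAS) is the
member position carrying the most read support, with ties broken to the
outermost position: the dominant molecule defines the isoform, and the
outermost tie-break is a stable, strand-aware rule. The representative
pair need not have been observed as a single molecule.

Three filters follow, in order:

1. **Support** — keep clusters with ≥ 3 read pairs.
2. **Mispriming** — oligo(dT) primers anneal to genomic A-rich tracts,
   fabricating 3′ ends. A cluster is discarded when the sense-strand
   genomic sequence within ±10 nt of its PAS contains ≥ 6 consecutive
   A's (a T-run on the forward reference for minus-strand clusters). We
   scan the genome directly rather than re-mapping A-tract reads; any
   run longer than 6 contains a 6-mer, so 6 is the active threshold.
   The ±10 nt scan window is a package default exposed as
   `polya_scan_flank`, since the biochemistry only bounds it loosely.
3. **TSS support** — paired-end capture is biased towards artifactual
   TSS calls near genic 3′ ends, so a cluster is kept only when its TSS
   falls inside an independent TSS-seq support interval extended by
   ±10 nt (`tss_support_flank`, boundary inclusive). This replaces an
   external peak caller with a containment test against intervals the
   user supplies; the filter's contract is overlap, not peak calling.

Stage counts are logged and must be monotonically non-increasing — a
pipeline invariant the tests assert.

## Classification model

Genome-wide summaries consider only genes whose interval intersects no
other gene **on either strand** (the strictest reading; it avoids
ambiguous assignment at nested or tail-to-tail loci at the price of
losing some genes). Each cluster is assigned to the intersecting
non-overlapping gene with maximal overlap, preferring same-strand genes;
clusters touching only opposite-strand genes are marked antisense.

Categories use the signed interior distances dT (cluster TSS vs
annotated TSS) and dP (cluster PAS vs annotated PAS), positive pointing
into the gene, and an explicit tolerance τ (default 100 nt): internal
initiation (dT > τ, dP ≤ τ), internal termination (dP > τ, dT ≤ τ),
internal both, 5′/3′ extended (boundary more than τ outside the gene
while the other end stays within τ), and full span otherwise. Published
pie-chart style category breakdowns typically rest on unpublished overlap
logic; the τ rule table is our explicit, testable reconstruction, and τ
is a parameter precisely because that boundary is a modelling choice.
"Expressed gene" means a gene with ≥ 1 sense-assigned final cluster —
the weakest self-contained definition; the mean isoforms per expressed
gene is computed over that set. Zero-count categories receive half the
minimum observable proportion (0.5/*n*) before log2 fold-changes, to keep
cross-genotype comparisons finite.

## sppRNA calling

Short promoter-proximal RNAs are capped, polyadenylated transcripts
terminated shortly after initiation. A final cluster is called when its
width is strictly under 350 nt, its TSS lies within ±40 nt of a
same-strand annotated TSS, and its span overlaps no annotated
termination site. "Termination sites" we interpret as same-strand
annotated gene 3′ ends — the conservative reading that removes
internal-termination look-alikes at short genes; a `termination_strand =
"both"` option covers the stricter interpretation. Gene-level statistics
report the fraction of expressed genes with ≥ 1 call and the median call
width. For cross-condition comparisons (sppRNA vs mRNA signal in two
conditions) the qualitative pattern of interest is mRNA up while sppRNA
down; we make it operational with a 1.5-fold threshold on both ratios
and +1 pseudocounts, both package choices, since only the pattern — not
a threshold — is established usage.

## Nascent-transcription metrics

Gene-body signal sums coverage over the gene shrunk 200 nt from each
boundary, avoiding the TSS- and PAS-proximal peaks that would otherwise
dominate. TPM here is the per-kb rate normalised to the per-kb-rate sum
over the analysed gene set, × 10⁶ — the standard construction, stated
explicitly because "TPM coverage" admits variants. The 5′ pausing index
is promoter TPM (TSS ± 150 nt) over body TPM (gene shrunk 300 nt per
side), restricted to non-overlapping genes longer than 1,000 nt within
the top 75% by gene-body signal *on the supplied track* (the ranking
source is a package choice; it keeps the computation self-contained).
Because numerator and denominator share the normaliser, the index is
invariant to global track scaling — a property the tests assert exactly.

Control genes with matched expression are drawn by binning target genes'
body signal into 10 quantile bins and sampling candidates per bin without
replacement, seeded; bins short of candidates are part-filled with a
warning. Ten bins reconstructs an unpublished matching procedure; the bin
count is a parameter. Metagene profiles average strand-oriented windows
around anchors with a normal-approximation 95% band (mean ± 1.96 × SEM),
appropriate at the anchor counts involved (hundreds to thousands).
Distribution comparisons use the two-sided Wilcoxon rank-sum test; fully
tied input returns p = 1 with a warning rather than an error.

## Motif scanning

Promoter windows are strand-oriented genomic slices around the TSS
anchor, reverse-complemented on minus-strand genes so "upstream" always
means 5′ of the anchor, with N-padding at chromosome edges. Three
presets ship: −200/+150 (display), −300/+50 and −20/+250 (discovery
windows). IUPAC patterns are matched with pattern-side degeneracy only
(`Biostrings` `fixed = "subject"`): `R` matches A/G, but an N in the
*sequence* matches nothing, so padding never fabricates hits. Overlapping
matches are all reported, on the given strand only; paired motifs such
as `HTGGGCY` and its reverse complement `RGCCCAW` are scanned as two
separate patterns. De novo discovery is out of scope — the scanner takes
user-supplied patterns, with the two promoter motifs above as bundled
defaults.

## The simulator: what it emulates, and what it does not

The generator exists so that every stage can be scored against known
truth. Its defaults encode the study conditions the pipeline targets:
2,000 genes, 200,000 molecules, mean 4.3 isoforms per gene
(zero-truncated Poisson), 14% of genes with an sppRNA isoform whose
length is lognormal with median 93 nt (sdlog 0.35, truncated to
[40, 349] nt — the lower bound keeps jittered molecules from inverting),
5% mispriming, 2% artifactual 5′ ends, and end-jitter from a rounded
zero-mean normal with sd 5 nt clamped at 3 sd per end (end heterogeneity
is real but unmodelled in the field; a bounded discretised normal is the
simplest defensible choice).

Structural choices worth knowing:

- Non-canonical isoform boundaries sit on a 60 nt grid at least 120 nt
  from the annotated boundary, so distinct isoforms can never chain into
  one cluster through jitter — alternative TSSs/PASs tens to hundreds of
  nt apart is the realistic regime for focused promoters.
- Internal-termination isoforms keep widths ≥ 420 nt so that none
  masquerades as an sppRNA; recovered sppRNA calls therefore measure the
  sppRNA subpopulation alone.
- One sense-strand A-tract of 6–9 nt is planted per gene, ≥ 360 nt from
  the TSS and ≥ 411 nt from the PAS, so planted tracts can trap
  misprimed molecules without vetoing true ends. Misprimed 3′ ends sit
  exactly at the tract (templated by genome, hence unjittered). Random
  sequence also contains chance A-runs (~0.5% of windows), which costs
  the pipeline a little recall honestly.
- Coverage simulation emits Poisson counts over gene bodies plus a
  150 nt upstream extension — nascent polymerase density begins just
  upstream of the annotated TSS — so a ±150 nt promoter window over
  uniform transcription yields a pausing index of 1; sppRNA genes
  receive a multiplicative promoter gain over the first 150 nt.

What passing recovery tests does **not** show about real data: the
simulator has no sequencing errors, no splicing, no chromatin- or
sequence-driven end preferences, dispersed-promoter shapes are uniform
rather than gene-class specific, and expression follows a gamma law with
no length bias. Recovery rates on simulated data are therefore upper
bounds, not forecasts, for real libraries.

## Numerical and degenerate-input policy

All window parameters are strictly positive and validated
(`PipelineParams`); merge and width thresholds are strict inequalities,
TSS-window containment is boundary inclusive — each boundary is pinned
by a test. Windows extending past chromosome ends truncate (filters) or
N-pad (sequence extraction) rather than erroring; metagene windows past
an edge are dropped and counted. Empty inputs propagate as empty outputs
except where silence would mislead: an empty TSS-support set removes
every cluster with a prominent warning, and an empty expressed-gene set
is an error. Zero gene-body signal makes the pausing index undefined
(excluded, with reason) rather than infinite. Ties in representative-end
selection break outward; assignment ties break to the leftmost gene.

## Problem sizes and verification scale

The bundled tests run the complete pipeline at 2,000 genes × 200,000
molecules once (the default study conditions, ~1 minute), cluster-merge
oracle equivalence on 100 random instances of up to 500 end-pairs against
an all-pairs transitive-closure oracle, 100-seed replications for
control-matching calibration (1,000 genes) and promoter-stalling
detection power (300 genes per set, gain 10), and exhaustive-enumeration
checks for the rank-sum test at small *n*. Deeper per-gene coverage
(600 molecules/gene) is used where the quantity under test — the mean
isoform count — is sensitive to the 3-read support floor; at 100
molecules/gene, isoforms with small expression shares drop below the
floor and the estimator reads low, which is a property of the method at
shallow coverage, not an estimator defect.

## Known limitations

- The category rule table and τ are a reconstruction; other reasonable
  overlap definitions shift proportions by a few points.
- The TSS-support filter is only as good as the supplied interval set;
  with sparse TSS-seq it removes genuine clusters.
- The mispriming filter removes true PASs that genuinely abut A-rich
  genome (~0.5% in random sequence; more in A-rich genomes).
- Single-linkage merging can chain through dense end-pair fields; the
  20 nt window keeps this rare at realistic isoform spacing, but very
  dispersed promoters may fuse.
- `compareConditions` thresholds (1.5-fold, +1 pseudocount) are
  conventions, not fitted values; conclusions should be robust to them.
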