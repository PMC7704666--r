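---
title: "Cluster-local background enrichment for broad histone marks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-local background enrichment for broad histone marks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterchip)
```

## The problem

Broad repressive histone marks such as H3K9me2, H3K27me2 and H3K27me3
spread over many kilobases and lack the sharp peaks that most ChIP-Seq
statistics are built around. Over a tandem gene cluster — the mouse Hox
loci (Hoxa–Hoxd, 39 genes, paralog groups 1–13) being the canonical
example — the question is not "where is the peak" but "did the mark's
level over each gene body change between two conditions", for example
wild-type versus a demethylase knockout.

clusterchip implements a per-gene, input-normalized contrast designed
for exactly this setting:

$$\mathrm{log_2FC}_g \;=\;
\log_2\!\left\{
\frac{\mathrm{CPM}^{IP1}_g / \mathrm{CPM}^{input1}_{c(g)}}
     {\mathrm{CPM}^{IP2}_g / \mathrm{CPM}^{input2}_{c(g)}}
\right\}$$

where CPM is reads per million mapped reads, the IP terms are counted
over the *gene body* of gene $g$, and the input terms over the *entire
cluster locus* $c(g)$ that contains the gene. Using the whole locus as
the background window is the key design point: input coverage over a
single gene is noisy at practical depths, and site-specific artifacts
(mappability, copy-number wobble, sonication bias) hit the IP and input
windows differently. The cluster-level input damps that noise while
remaining local enough to absorb regional biases shared by IP and
input. The statistic is computed per replicate pair and the replicate
log2 values are averaged arithmetically (the log of the geometric mean
ratio), then laid out as a clusters × paralog-group matrix read
anterior→posterior.

Two cancellations make the double ratio robust:

* **Depth** cancels exactly through CPM; duplicating every read changes
  nothing.
* **Gene length and mappability** cancel between conditions: any factor
  that scales a gene's IP counts identically in both conditions drops
  out, so no per-kilobase correction is needed.

## Counting contract

A cluster locus is the span from the first member gene to the last
(`build_cluster_loci()`), and one combined annotation carries both
feature classes (`write_counting_annotation()`), so a single counting
pass serves gene bodies and loci. The counting rules
(`counting_config()`) mirror the established broad-mark convention:

| parameter | default | why |
|---|---|---|
| 3' extension | 500 bp | extend single-end reads to the sonicated fragment size so coverage reflects fragments, not read ends |
| multimappers | counted at every reported location | repressive domains sit in repeat-rich DNA; dropping multimappers biases them down (secondary alignments are retained at load time) |
| multi-overlap | count once per overlapped feature | gene bodies are nested inside their cluster locus by construction, so features overlap by design; integer counting per feature |
| strand | ignored | ChIP fragments carry no strand information |
| overlap threshold | ≥ 1 bp | the standard feature-counting default |

The library size used as every CPM denominator is the retained-record
count after one explicit filter: mapped primary and secondary records
kept, unmapped and supplementary dropped, no MAPQ cut, no duplicate
removal. Paired-end input is rejected outright rather than
half-counted; the semantics here are defined for single-end libraries
(the motivating data are single-end 36-bp reads).

## Tunable parameters that matter

* `pseudocount` (default 0): with a cluster-wide background window a
  zero denominator indicates a broken library, not sparseness, so the
  default is a hard error naming the offending term and gene. For toy
  or very shallow data a small pseudocount (e.g. 1 CPM) is available;
  it shrinks extreme ratios toward 0.
* `numerator_condition` (default 1): which condition sits in the
  numerator; positive values mean enriched in that condition. The run
  log records the mapping because heatmap display direction is
  otherwise ambiguous.
* Replicates are paired by replicate index across the four roles (IP
  and input in both conditions). Averaging happens after the log, per
  replicate pair.
* Coverage tracks (`binned_cpm_track()`): 50-bp bins with 500-bp
  5'-anchored fragment extension for ChIP; 1-bp bins without extension
  for RNA-style tracks. A bin's value is the number of overlapping
  extended reads × 10⁶ / library size, so a bin never exceeds 10⁶ and
  reads wholly inside single bins conserve total mass at exactly 10⁶.

## Numerical choices

* The contrast is computed as
  `log2((ip1+p)/(in1+p)) - log2((ip2+p)/(in2+p))`, a *difference of two
  log ratios* rather than the log of the four-term quotient. The two
  are mathematically identical, but the difference form makes exchange
  of condition labels an exact IEEE negation (x − y = −(y − x)
  bitwise), so antisymmetry holds to the last bit, not just to
  rounding.
* Reverse-strand extension is clamped at position 1 (and at the contig
  end when lengths are known); degenerate placements can shorten an
  extended interval but never produce invalid coordinates.
* Missing paralog groups are `NA` in the matrix, never 0: a zero is a
  measured "no change", which an absent gene is not.
* Intervals are held as `GRanges` (1-based, closed), the native R
  container for genomic arithmetic; GTF (1-based) and BED (0-based
  half-open) conventions are handled at the I/O boundary by
  rtracklayer. Browser-style text coordinates round-trip unchanged
  through `parse_region()`/`format_region()`.

## The simulator, and what passing tests do and do not show

`simulate_annotation()` lays out clusters of non-overlapping genes on
one pseudo-contig per cluster (defaults: 4 clusters × 10 genes, ~2 kb
genes, ~8 kb spacing — a miniature of the Hox geometry).
`simulate_truth()` assigns each gene an enrichment multiplier per
condition; the true contrast is `log2(multiplier_c1/multiplier_c2)`,
drawn from {−1, −0.5, 0, +0.5, +1}, on top of a baseline IP enrichment
of 2× over background in both conditions. `simulate_libraries()` then
emits single-end 36-bp SAM libraries of exactly the requested depth:
input fragment starts uniform over each locus (extended upstream by the
500-bp fragment margin), IP fragment starts weighted by the gene
multiplier inside gene bodies and by 1 elsewhere; strands are
Bernoulli(1/2), with reverse-strand 5' ends placed so the 3'-extended
read covers the sampled fragment regardless of strand. Everything is
deterministic under a seed (each library draws from its own derived
substream; the caller's RNG state is untouched).

Validation runs at 2 × 10⁵ reads per library (eight libraries: two
conditions × IP/input × two replicates) recover the truth with a mean
absolute error below 0.15 log2 units and perfect sign concordance for
|true log2FC| ≥ 0.5. A small systematic component of that error is
expected and understood: because every library is normalized to its own
total, condition-wide differences in total IP mass shift all genes by
log2 of the ratio of normalization totals (≈ 0.04 under the default
geometry). The same effect exists in any CPM-normalized comparison of
real libraries; the cluster-local input background does not remove it.

The simulator emulates read geometry, uniform background, broad
gene-body enrichment and replicate structure. It does **not** model
sequencing error, GC or mappability bias, duplicate structure, or
chromatin outside the cluster neighborhoods — so passing recovery tests
demonstrates correctness of the estimator under its own assumptions,
not robustness to genome-scale artifacts. Genome-scale results require
real aligned libraries.

The bundled `hox_fixture()` encodes the standard 39-gene mouse Hox
complement in four clusters with the clusters' mm10 boundary
coordinates; gene placement *inside* each cluster is synthetic (evenly
spaced, boundary genes pinned), which is sufficient for testing
annotation logic and display layout but is not a real gene model.

## Problem sizes used by the test suite

The suite validates with 50-seed antisymmetry sweeps at 500 reads per
library, a 1 000-read × 50-feature brute-force counting oracle, and one
full-depth (2 × 10⁵ reads/library) recovery run — sizes chosen so the
whole suite completes in about a minute while the recovery run still
operates at the depth regime the estimator targets.

## Known limitations

* Two conditions only; multi-condition designs need repeated pairwise
  runs.
* No statistical test is attached to the per-gene contrasts; the output
  is an effect-size matrix, as in the motivating analysis.
* Fractional multimapper weighting and exon-aware counting are out of
  scope; counting is whole-gene-body and integer.
* `--exactScaling`-style bit-for-bit emulation of external track tools
  is a non-goal; the coverage contract above is the specification.
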