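# clusterchip

Condition contrasts of **broad histone marks over tandem gene
clusters**, for ChIP-Seq analysts working on loci like the mouse Hox
clusters (Hoxa–Hoxd; 39 genes, paralog groups 1–13) where repressive
marks such as H3K9me2 or H3K27me2/me3 form domains rather than peaks
and the question is a per-gene *level change* between two conditions.

## The statistic

For gene *g* in cluster *c(g)*, with two conditions (e.g. wild-type vs
knockout), the per-gene input-normalized log2 fold-change is

```
log2FC_g = log2{ (CPM_IP1[g] / CPM_input1[c(g)]) /
                 (CPM_IP2[g] / CPM_input2[c(g)]) }
```

where CPM is reads per million mapped reads, the IP terms are counted
over the **gene body**, and the input terms over the **entire cluster
locus** — a cluster-local background that damps site-specific input
noise while staying local enough to absorb regional bias. Reads are
extended 500 bp at the 3' end before counting (multimappers and
multi-overlap counted; strand ignored), the contrast is computed per
replicate pair, replicate log2 values are averaged, and the result is
laid out as a clusters × paralog-group matrix read anterior→posterior.

The package also provides binned CPM coverage tracks (bedGraph),
ChIP-qPCR percent-of-input arithmetic, the padj < 0.05 / TPM > 1
differential-expression filter rule, and a seeded single-end 36-bp
read simulator with per-gene ground-truth enrichment multipliers, so
the whole pipeline is testable without any external data.

## Worked example

Simulate a four-cluster, 40-gene annotation with known per-gene
enrichment, generate eight libraries (2 conditions × IP/input × 2
replicates, 50 000 reads each), and run the pipeline:

```r
library(clusterchip)

sim   <- simulate_annotation(n_clusters = 4, genes_per_cluster = 10, seed = 1)
truth <- simulate_truth(sim$genes, seed = 1)
sheet <- simulate_libraries(sim, truth, "demo", depth = 50000,
                            replicates = 2, seed = 1)

cfg <- structure(list(annotation = attr(sheet, "annotation_path"),
                      cluster_membership = attr(sheet, "membership_path"),
                      sample_sheet = attr(sheet, "sheet_path"),
                      mark = "H3K9me2", pseudocount = 0,
                      extension_3prime_bp = 500, numerator_condition = 1L,
                      seed = 1L, out_dir = "demo/res"),
                 class = "pipeline_config")
enr <- run_pipeline(cfg)
print(enr)
```

```
cluster_enrichment for mark H3K9me2 (condition 1 in the numerator; 2 replicate(s))
              1      2      3      4      5      6      7      8      9     10
cluster1 -0.842  0.496 -0.943 -0.477  0.857  0.094 -0.477 -0.069 -0.083 -0.890
cluster2  0.945  0.935 -0.525 -0.285 -0.896  1.003  0.800 -0.760 -0.914  0.850
cluster3  1.037 -0.389 -0.377 -0.957  0.518 -0.919  0.457  0.009 -0.405 -0.392
cluster4  0.296  0.499  0.366 -0.620  0.449 -0.915 -0.855  0.387 -0.667 -0.429
```

Rows are clusters, columns paralog positions (anterior → posterior);
each entry is the replicate-averaged log2 fold-change, positive =
enriched in condition 1. Comparing against the simulator's truth table
(true values drawn from {−1, −0.5, 0, +0.5, +1}):

```r
m <- merge(enr$long, truth, by = "gene_id")
mean(abs(m$mean_log2fc - m$truth_log2fc))
#> 0.096
head(m[, c("gene_id", "truth_log2fc", "mean_log2fc")], 3)
#>        gene_id truth_log2fc mean_log2fc
#> 1 cluster1_g01         -1.0  -0.8420086
#> 2 cluster1_g02          0.5   0.4960402
#> 3 cluster1_g03         -1.0  -0.9431004
```

At this depth the recovered values track the truth to within ~0.1 log2
units. The run directory also gets `heatmap.tsv`,
`enrichment_long.tsv`, `counts.tsv` (+ library-size JSON) and
`run_log.json` recording every parameter, library size and the
condition→numerator mapping.

The bundled deterministic annotation `hox_fixture()` carries the
39-gene mouse Hox complement with the four clusters' mm10 boundary
coordinates (`format_region(hox_fixture()$clusters)` prints
`chr6:52155590-52260880` and friends); gene placement inside each
cluster is synthetic.

A thin CLI wrapper with `run`, `simulate`, `count`, `enrich`,
`coverage`, `qpcr` and `de-filter` subcommands is installed at
`inst/scripts/clusterchip`.

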