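Package: clusterchip
Title: Cluster-Local-Background ChIP-Seq Enrichment for Gene Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies condition contrasts of broad histone marks
    (e.g. H3K9me2, H3K27me2/me3) over tandem gene clusters such as the
    mouse Hox loci. Computes per-gene, input-normalized log2 enrichment
    ratios in which the immunoprecipitation signal is counted over gene
    bodies while the input background is counted over the entire cluster
    locus, damping site-specific noise. Includes feature counting with
    3' read extension, CPM normalization, binned coverage tracks,
    ChIP-qPCR percent-of-input arithmetic, a differential-expression
    filter rule, a seeded synthetic read simulator with ground-truth
    enrichment multipliers for validation, and an end-to-end pipeline
    producing anterior-to-posterior cluster heatmaps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
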