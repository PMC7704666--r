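test_that("contrast_log2fc matches hand arithmetic", {
  expect_equal(contrast_log2fc(1, 1, 1, 1), 0)
  # (300/200) / (150/200) = 1.5 / 0.75 = 2 -> log2 = 1
  expect_equal(contrast_log2fc(300, 200, 150, 200), 1)
  expect_equal(contrast_log2fc(5, 10, 40, 20), log2((5 / 10) / (40 / 20)))
})

test_that("exchanging conditions negates the contrast bitwise", {
  set.seed(3)
  for (i in 1:50) {
    v <- runif(4, 0.01, 1000)
    a <- contrast_log2fc(v[1], v[2], v[3], v[4])
    b <- contrast_log2fc(v[3], v[4], v[1], v[2])
    expect_identical(a, -b)
  }
})

test_that("zero denominators error by default, pseudocount rescues", {
  expect_error(contrast_log2fc(10, 0, 5, 5, gene_id = "gX"),
               "input1.*gX")
  expect_error(contrast_log2fc(10, 5, 0, 5), "ip2")
  expect_equal(contrast_log2fc(10, 0, 5, 5, pseudocount = 1),
               log2(11 / 1) - log2(6 / 6))
  expect_error(contrast_log2fc(-1, 1, 1, 1), "non-negative")
})

test_that("replicate averaging is the arithmetic mean of log2 values", {
  expect_equal(average_replicates(1), 1)
  expect_equal(average_replicates(c(1, 0.5)), 0.75)
  expect_equal(average_replicates(c(-1, 1)), 0)
  expect_error(average_replicates(numeric(0)), "no replicate")
})

# A hand-sized scenario: 2 genes / 1 cluster / 2 replicates. Counts are
# chosen so the expected per-replicate values are exact.
make_toy_scenario <- function(counts_gA_ip1 = c(300L, 150L)) {
  libs <- c("ip1r1", "ip1r2", "in1r1", "in1r2",
            "ip2r1", "ip2r2", "in2r1", "in2r2")
  counts <- matrix(0L, nrow = 3, ncol = 8,
                   dimnames = list(c("gA", "gB", "cl1"), libs))
  counts["gA", ] <- c(counts_gA_ip1, 200L, 200L, 150L, 150L, 200L, 200L)
  counts["gB", ] <- c(100L, 100L, 200L, 200L, 100L, 100L, 200L, 200L)
  counts["cl1", ] <- c(500L, 400L, 200L, 200L, 300L, 350L, 200L, 200L)
  tab <- toy_count_table(
    counts,
    feature_class = c(gA = "gene_body", gB = "gene_body",
                      cl1 = "cluster_locus"),
    library_sizes = stats::setNames(rep(1e6, 8), libs))
  sheet <- data.frame(
    library_id = libs,
    role = rep(c("IP", "input", "IP", "input"), each = 2),
    mark = "H3K9me2",
    condition = rep(c(1L, 2L), each = 4),
    replicate = rep(1:2, 4),
    path = NA_character_)
  list(tab = tab, sheet = sheet)
}

test_that("heatmap assembly pairs replicates and averages after the log", {
  sc <- make_toy_scenario()
  genes <- toy_gene_set()
  clusters <- toy_clusters(genes)
  enr <- compute_cluster_heatmap(sc$tab, genes, clusters, sc$sheet,
                                 mark = "H3K9me2")
  # gA rep1: IP cpm ratio vs cluster-locus input background
  r1 <- log2(300 / 200) - log2(150 / 200)
  r2 <- log2(150 / 200) - log2(150 / 200)
  gA <- enr$long[enr$long$gene_id == "gA", ]
  expect_equal(gA$log2fc_rep1, r1)
  expect_equal(gA$log2fc_rep2, r2)
  expect_equal(gA$mean_log2fc, mean(c(r1, r2)))
  # matrix layout: 1 cluster x paralogs 1..2
  expect_equal(dim(enr$matrix), c(1L, 2L))
  expect_equal(enr$matrix["cl1", "1"], gA$mean_log2fc)
})

test_that("scaling a gene's IP counts in both conditions cancels", {
  sc1 <- make_toy_scenario()
  genes <- toy_gene_set(); clusters <- toy_clusters(genes)
  e1 <- compute_cluster_heatmap(sc1$tab, genes, clusters, sc1$sheet,
                                mark = "H3K9me2")
  # triple gA's IP counts in conditions 1 AND 2 (gene-length surrogate)
  sc2 <- make_toy_scenario()
  sc2$tab$counts["gA", c("ip1r1", "ip1r2", "ip2r1", "ip2r2")] <-
    3L * sc2$tab$counts["gA", c("ip1r1", "ip1r2", "ip2r1", "ip2r2")]
  e2 <- compute_cluster_heatmap(sc2$tab, genes, clusters, sc2$sheet,
                                mark = "H3K9me2")
  expect_equal(e2$long$mean_log2fc, e1$long$mean_log2fc)
})

test_that("numerator condition flips the sign convention", {
  sc <- make_toy_scenario()
  genes <- toy_gene_set(); clusters <- toy_clusters(genes)
  e1 <- compute_cluster_heatmap(sc$tab, genes, clusters, sc$sheet,
                                mark = "H3K9me2", numerator_condition = 1)
  e2 <- compute_cluster_heatmap(sc$tab, genes, clusters, sc$sheet,
                                mark = "H3K9me2", numerator_condition = 2)
  expect_identical(e1$matrix, -e2$matrix)
})

test_that("heatmap preconditions fail loudly", {
  sc <- make_toy_scenario()
  genes <- toy_gene_set(); clusters <- toy_clusters(genes)
  # unequal replicate counts
  sheet_bad <- sc$sheet[sc$sheet$library_id != "ip1r2", ]
  expect_error(compute_cluster_heatmap(sc$tab, genes, clusters, sheet_bad,
                                       mark = "H3K9me2"),
               "unequal replicate")
  # missing role/condition
  sheet_bad2 <- sc$sheet[!(sc$sheet$role == "input" &
                             sc$sheet$condition == 2L), ]
  expect_error(compute_cluster_heatmap(sc$tab, genes, clusters,
                                       sheet_bad2, mark = "H3K9me2"),
               "input/condition 2")
  # gene without a cluster
  orphan <- genes
  orphan$cluster_id[2] <- NA
  expect_error(compute_cluster_heatmap(sc$tab, orphan, clusters, sc$sheet,
                                       mark = "H3K9me2"),
               "without cluster")
})

test_that("absent paralogs are missing, not zero, in the matrix", {
  hox <- hox_fixture()
  libs <- c("ip1", "in1", "ip2", "in2")
  fid <- c(hox$genes$gene_id, names(hox$clusters))
  counts <- matrix(50L, nrow = length(fid), ncol = 4,
                   dimnames = list(fid, libs))
  tab <- toy_count_table(
    counts,
    feature_class = stats::setNames(
      rep(c("gene_body", "cluster_locus"), c(39, 4)), fid),
    library_sizes = stats::setNames(rep(1e6, 4), libs))
  sheet <- data.frame(library_id = libs,
                      role = c("IP", "input", "IP", "input"),
                      mark = "H3K9me2", condition = c(1L, 1L, 2L, 2L),
                      replicate = 1L, path = NA_character_)
  enr <- compute_cluster_heatmap(tab, hox$genes, hox$clusters, sheet,
                                 mark = "H3K9me2")
  expect_equal(dim(enr$matrix), c(4L, 13L))
  # Hoxa has no paralog 8 or 12; Hoxc starts at 4
  expect_true(is.na(enr$matrix["Hoxa", "8"]))
  expect_true(is.na(enr$matrix["Hoxa", "12"]))
  expect_true(is.na(enr$matrix["Hoxc", "1"]))
  expect_false(anyNA(enr$matrix["Hoxb", as.character(1:7)]))
  # equal counts everywhere -> flat zero enrichment where defined
  expect_true(all(enr$matrix[!is.na(enr$matrix)] == 0))
})

test_that("enrichment TSVs round-trip the matrix and long form", {
  sc <- make_toy_scenario()
  genes <- toy_gene_set(); clusters <- toy_clusters(genes)
  enr <- compute_cluster_heatmap(sc$tab, genes, clusters, sc$sheet,
                                 mark = "H3K9me2")
  mp <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_enrichment(enr, mp, lp)
  m <- read.delim(mp, check.names = FALSE)
  expect_equal(as.numeric(m[1, -1]), unname(enr$matrix[1, ]))
  l <- read.delim(lp)
  expect_equal(l$mean_log2fc, enr$long$mean_log2fc)
})
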