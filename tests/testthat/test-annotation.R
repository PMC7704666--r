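test_that("region strings round-trip through parse and format", {
  x <- "chr6:52155590-52260880"
  expect_identical(format_region(parse_region(x)), x)

  set.seed(42)
  for (i in 1:25) {
    s <- sample.int(1e8, 1)
    gr <- GenomicRanges::GRanges(
      sample(c("chr1", "chrX", "ctg_7"), 1),
      IRanges::IRanges(s, s + sample.int(1e6, 1)))
    expect_identical(parse_region(format_region(gr)), gr)
  }
  expect_error(parse_region("chr1:oops"), "malformed")
  expect_error(parse_region("chr1:500-100"), "exceeds")
})

test_that("GTF gene records load with 1-based inclusive coordinates", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr6\ttoy\tgene\t52155590\t52260880\t.\t+\t.\t",
                    'gene_id "g1"; gene_name "Hoxa1";'), gtf)
  gs <- load_gene_models(gtf)
  expect_length(gs, 1)
  expect_equal(GenomicRanges::start(gs), 52155590)
  expect_equal(GenomicRanges::end(gs), 52260880)
  expect_identical(gs$gene_id, "g1")
  expect_identical(format_region(gs), "chr6:52155590-52260880")
})

test_that("toy GTF matches hand parsing; empty file gives empty set", {
  gtf <- tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\ttoy\tgene\t100\t200\t.\t+\t.\tgene_id "a"; gene_name "A";',
    'chr1\ttoy\tgene\t300\t450\t.\t-\t.\tgene_id "b"; gene_name "B";',
    'chr2\ttoy\tgene\t10\t20\t.\t+\t.\tgene_id "c"; gene_name "C";')
  writeLines(lines, gtf)
  gs <- load_gene_models(gtf)
  expect_length(gs, 3)
  expect_identical(gs$gene_id, c("a", "b", "c"))
  expect_equal(GenomicRanges::start(gs), c(100, 300, 10))
  expect_equal(GenomicRanges::end(gs), c(200, 450, 20))
  expect_identical(as.character(GenomicRanges::seqnames(gs)),
                   c("chr1", "chr1", "chr2"))

  empty <- tempfile(fileext = ".gtf")
  writeLines("# nothing here", empty)
  expect_length(load_gene_models(empty), 0)
})

test_that("malformed GTF lines and duplicate gene_ids are rejected", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\ttoy\tgene\t100\t200\t.\t+\t.\tgene_id "a";',
               "chr1\tbroken line"), gtf)
  expect_error(load_gene_models(gtf), "line 2")

  dup <- tempfile(fileext = ".gtf")
  writeLines(rep(
    'chr1\ttoy\tgene\t100\t200\t.\t+\t.\tgene_id "a";', 2), dup)
  expect_error(load_gene_models(dup), "duplicate gene_id")
})

test_that("BED input is converted from 0-based half-open", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr6\t52155589\t52260880\tg1\t0\t+", bed)
  gs <- load_gene_models(bed)
  expect_equal(GenomicRanges::start(gs), 52155590)
  expect_equal(GenomicRanges::end(gs), 52260880)
})

test_that("cluster loci span first to last member gene", {
  # boundary fixture: members' min start / max end give the printed span
  genes <- GenomicRanges::GRanges(
    "chr6", IRanges::IRanges(c(52155590, 52200000, 52255000),
                             c(52158000, 52205000, 52260880)))
  GenomicRanges::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = c("g1", "g2", "g3"), gene_name = c("g1", "g2", "g3"),
    cluster_id = NA_character_, paralog_number = NA_integer_)
  cl <- build_cluster_loci(genes, list(Hoxa = c("g1", "g2", "g3")))
  expect_identical(format_region(cl), "chr6:52155590-52260880")
  expect_identical(cl$members[[1]], c("g1", "g2", "g3"))

  # single-gene cluster: locus equals the gene interval
  one <- build_cluster_loci(genes[1], list(solo = "g1"))
  expect_equal(GenomicRanges::start(one), GenomicRanges::start(genes[1]))
  expect_equal(GenomicRanges::end(one), GenomicRanges::end(genes[1]))
})

test_that("cluster loci equal brute-force min/max and ignore member order", {
  set.seed(7)
  for (i in 1:10) {
    n <- 5
    s <- sample.int(1e6, n)
    genes <- GenomicRanges::GRanges(
      "chr9", IRanges::IRanges(s, s + sample.int(5e4, n)))
    GenomicRanges::mcols(genes) <- S4Vectors::DataFrame(
      gene_id = paste0("g", 1:n), gene_name = paste0("g", 1:n),
      cluster_id = NA_character_, paralog_number = NA_integer_)
    ids <- sample(genes$gene_id)  # shuffled membership order
    cl <- build_cluster_loci(genes, list(k = ids))
    expect_equal(GenomicRanges::start(cl), min(GenomicRanges::start(genes)))
    expect_equal(GenomicRanges::end(cl), max(GenomicRanges::end(genes)))
    # members reported in ascending genomic start, not input order
    expect_identical(cl$members[[1]],
                     genes$gene_id[order(GenomicRanges::start(genes))])
    # every member interval within the locus
    expect_true(all(IRanges::overlapsAny(
      genes, cl, type = "within", ignore.strand = TRUE)))
  }
})

test_that("cluster construction errors are informative", {
  genes <- toy_gene_set()
  expect_error(build_cluster_loci(genes, list()), "empty")
  expect_error(build_cluster_loci(genes, list(k = character())),
               "no members")
  expect_error(build_cluster_loci(genes, list(k = c("gA", "nope"))),
               "unknown gene_id")
  split_genes <- GenomicRanges::GRanges(
    c("chrT", "chrU"), IRanges::IRanges(c(100, 100), width = 50))
  GenomicRanges::mcols(split_genes) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"), gene_name = c("gA", "gB"),
    cluster_id = NA_character_, paralog_number = NA_integer_)
  expect_error(build_cluster_loci(split_genes, list(k = c("gA", "gB"))),
               "multiple chromosomes")
})

test_that("counting annotation combines gene bodies and cluster loci", {
  genes <- toy_gene_set()
  clusters <- toy_clusters(genes)

  f0 <- tempfile(fileext = ".gtf")
  write_counting_annotation(genes[0], clusters[0], f0)
  expect_true(all(grepl("^#", readLines(f0))))

  f1 <- tempfile(fileext = ".gtf")
  write_counting_annotation(genes, clusters, f1)
  body <- grep("^#", readLines(f1), value = TRUE, invert = TRUE)
  expect_length(body, 3)  # 2 gene bodies + 1 cluster locus

  re <- load_counting_annotation(f1)
  expect_identical(re$genes$gene_id, genes$gene_id)
  expect_equal(GenomicRanges::start(re$genes), GenomicRanges::start(genes))
  expect_identical(format_region(re$clusters), format_region(clusters))
})

test_that("Hox fixture reconstructs the printed cluster loci", {
  hox <- hox_fixture()
  expect_length(hox$genes, 39)
  expect_length(hox$clusters, 4)
  expect_identical(
    format_region(hox$clusters),
    c("chr6:52155590-52260880", "chr11:96194316-96368256",
      "chr15:102921103-103036852", "chr2:74668310-74765142"))
  expect_equal(max(hox$genes$paralog_number), 13)
  # 39 + 4 = 43 counting features
  f <- tempfile(fileext = ".gtf")
  write_counting_annotation(hox$genes, hox$clusters, f)
  expect_length(grep("^#", readLines(f), invert = TRUE), 43)
})

test_that("membership can be inferred from gene-name prefixes", {
  hox <- hox_fixture()
  inferred <- infer_cluster_membership(hox$genes)
  expect_setequal(names(inferred), c("Hoxa", "Hoxb", "Hoxc", "Hoxd"))
  expect_length(inferred$Hoxa, 11)
  expect_length(inferred$Hoxd, 9)
})
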