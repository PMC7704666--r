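# Shared fixture builders. Everything is generated in code at test time.

# Write a SAM file from a record table; seqs declares @SQ contigs.
write_toy_sam <- function(records, path,
                          seqs = c(chrT = 100000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), as.integer(seqs)))
  lines <- header
  if (nrow(records)) {
    lines <- c(lines, sprintf(
      "%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
      records$qname, records$flag, records$rname, records$pos,
      records$cigar))
  }
  writeLines(lines, path)
  path
}

sam_record <- function(qname, flag = 0L, rname = "chrT", pos = 1L,
                       cigar = "36M") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = cigar, stringsAsFactors = FALSE)
}

# A minimal alignment_set built directly from a GRanges (bypasses file
# I/O where the test is about downstream arithmetic, not parsing).
as_alignment_set <- function(reads, library_id = "lib") {
  structure(list(reads = reads, library_size = length(reads),
                 library_id = library_id),
            class = "alignment_set")
}

# Two genes in one cluster on one contig; handy for enrichment tests.
toy_gene_set <- function() {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1001, 5001), width = 1000), strand = "+")
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"), gene_name = c("gA", "gB"),
    cluster_id = "cl1", paralog_number = 1:2)
  names(gr) <- gr$gene_id
  gr
}

toy_clusters <- function(genes = toy_gene_set()) {
  build_cluster_loci(genes, list(cl1 = genes$gene_id), annotate = FALSE)
}

# Hand-assembled count_table (zeros explicit), for enrichment tests that
# need exact CPM inputs.
toy_count_table <- function(counts, feature_class, library_sizes) {
  structure(list(counts = counts, feature_class = feature_class,
                 library_sizes = library_sizes),
            class = "count_table")
}

# Independent brute-force overlap counter: all-pairs interval
# intersection with 3' extension, used as the oracle for
# count_features(). Deliberately naive; shares no code with the
# implementation.
brute_force_counts <- function(reads_df, features_df, ext) {
  # reads_df: chrom, pos (1-based leftmost), len, strand
  # features_df: feature_id, chrom, start, end (1-based closed)
  n <- nrow(features_df)
  out <- integer(n)
  for (i in seq_len(nrow(reads_df))) {
    r <- reads_df[i, ]
    if (r$strand == "+") {
      rs <- r$pos; re <- r$pos + r$len - 1 + ext
    } else {
      rs <- max(1, r$pos - ext); re <- r$pos + r$len - 1
    }
    for (j in seq_len(n)) {
      f <- features_df[j, ]
      if (f$chrom == r$chrom && rs <= f$end && re >= f$start) {
        out[j] <- out[j] + 1L
      }
    }
  }
  stats::setNames(out, features_df$feature_id)
}

# Build the pipeline_config list directly (no YAML file needed).
make_config <- function(sheet, out_dir, mark = "H3K9me2",
                        pseudocount = 0, numerator_condition = 1L) {
  structure(list(annotation = attr(sheet, "annotation_path"),
                 cluster_membership = attr(sheet, "membership_path"),
                 sample_sheet = attr(sheet, "sheet_path"),
                 mark = mark, pseudocount = pseudocount,
                 extension_3prime_bp = 500,
                 numerator_condition = numerator_condition,
                 seed = 1L, out_dir = out_dir),
            class = "pipeline_config")
}
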