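# Run expr under a private RNG stream; the caller's .Random.seed is
# untouched.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a clustered gene annotation
#'
#' Places `n_clusters` clusters, one per pseudo-contig, each with
#' `genes_per_cluster` non-overlapping genes laid left to right in
#' ascending paralog order (the default geometry mimics the four mouse
#' Hox clusters). Gene lengths and inter-gene gaps are jittered
#' uniformly within +/-25% of their nominal values, so the layout is
#' random but deterministic under `seed`.
#'
#' @param n_clusters,genes_per_cluster Counts, >= 1.
#' @param gene_length_bp Nominal gene-body length.
#' @param spacing_bp Nominal intergenic gap; must leave room for
#'   non-overlap after jitter (i.e. >= 4/3, so the jittered gap is >= 1).
#' @param seed Integer seed.
#' @param contig_pad_bp Bases appended after the last gene (and kept
#'   before the first) so extended fragments stay on the contig.
#' @return List with `genes`, `clusters` and `contig_lengths` (named
#'   vector).
#' @export
simulate_annotation <- function(n_clusters = 4, genes_per_cluster = 10,
                                gene_length_bp = 2000, spacing_bp = 8000,
                                seed = 1, contig_pad_bp = 2000) {
  stopifnot(n_clusters >= 1, genes_per_cluster >= 1, gene_length_bp >= 1,
            spacing_bp >= 1)
  if (floor(0.75 * spacing_bp) < 1 || floor(0.75 * gene_length_bp) < 1) {
    stop("geometry forces overlapping genes: ",
         "gene_length_bp and spacing_bp too small for the jitter")
  }
  .with_seed(seed, {
    per_cluster <- lapply(seq_len(n_clusters), function(ci) {
      lens <- floor(gene_length_bp * runif(genes_per_cluster, 0.75, 1.25))
      gaps <- floor(spacing_bp * runif(genes_per_cluster, 0.75, 1.25))
      starts <- contig_pad_bp + 1 + cumsum(c(0, (lens + gaps)[-genes_per_cluster]))
      gr <- GRanges(sprintf("chrS%d", ci),
                    IRanges(starts, width = lens), strand = "+")
      cid <- sprintf("cluster%d", ci)
      mcols(gr) <- DataFrame(
        gene_id = sprintf("%s_g%02d", cid, seq_len(genes_per_cluster)),
        gene_name = sprintf("Sim%d-%d", ci, seq_len(genes_per_cluster)),
        cluster_id = cid,
        paralog_number = seq_len(genes_per_cluster))
      gr
    })
    genes <- .as_gene_set(suppressWarnings(do.call(c, per_cluster)))
    membership <- split(genes$gene_id, genes$cluster_id)
    clusters <- build_cluster_loci(genes, membership, annotate = FALSE)
    contig_lengths <- vapply(per_cluster, function(g) {
      max(end(g)) + contig_pad_bp
    }, 0)
    names(contig_lengths) <- sprintf("chrS%d", seq_len(n_clusters))
    list(genes = genes, clusters = clusters,
         contig_lengths = contig_lengths)
  })
}

#' Draw per-gene ground-truth enrichment multipliers
#'
#' Assigns each gene an enrichment multiplier per condition such that
#' the true log2 fold-change, `log2(multiplier_c1 / multiplier_c2)`, is
#' drawn uniformly from `log2fc_levels`. Condition 2 keeps the baseline
#' multiplier (broad-mark IP enrichment over background); condition 1
#' carries the contrast.
#'
#' @param genes Gene set.
#' @param log2fc_levels True log2 fold-change levels to sample from.
#' @param base_multiplier IP enrichment of a gene body over the
#'   locus background common to both conditions (>= 0).
#' @param seed Integer seed.
#' @return Data frame `gene_id, multiplier_c1, multiplier_c2,
#'   truth_log2fc` — the truth table consumed by recovery tests.
#' @export
simulate_truth <- function(genes,
                           log2fc_levels = c(-1, -0.5, 0, 0.5, 1),
                           base_multiplier = 2, seed = 1) {
  .with_seed(seed, {
    truth <- sample(log2fc_levels, length(genes), replace = TRUE)
    data.frame(gene_id = genes$gene_id,
               multiplier_c1 = base_multiplier * 2^truth,
               multiplier_c2 = rep(base_multiplier, length(genes)),
               truth_log2fc = truth)
  })
}

# Sample `depth` fragment-start positions (1-based) over the union of
# cluster sampling domains, weighted per base: `multiplier` inside gene
# bodies (IP of that condition), 1 elsewhere; input libraries weight 1
# everywhere. Returns data.frame(chrom, fstart).
.sample_fragment_starts <- function(genes, clusters, multipliers, depth,
                                    fragment_bp) {
  segs <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    chrom <- as.character(seqnames(cl))
    dom_s <- max(1L, start(cl) - fragment_bp)
    dom_e <- end(cl)
    g <- genes[genes$cluster_id == names(clusters)[ci]]
    g <- g[order(start(g))]
    # breakpoints: alternating background / gene segments
    cuts_s <- pmax(start(g), dom_s); cuts_e <- pmin(end(g), dom_e)
    bounds <- sort(unique(c(dom_s, dom_e + 1L, cuts_s, cuts_e + 1L)))
    s <- bounds[-length(bounds)]; e <- bounds[-1L] - 1L
    w <- rep(1, length(s))
    for (k in seq_along(g)) {
      inside <- s >= start(g)[k] & e <= end(g)[k]
      w[inside] <- multipliers[[g$gene_id[k]]]
    }
    segs[[ci]] <- data.frame(chrom = chrom, s = s, e = e, w = w)
  }
  segs <- do.call(rbind, segs)
  mass <- segs$w * (segs$e - segs$s + 1)
  if (all(mass == 0)) stop("all sampling mass is zero")
  idx <- sample.int(nrow(segs), depth, replace = TRUE, prob = mass)
  off <- floor(runif(depth) * (segs$e[idx] - segs$s[idx] + 1))
  data.frame(chrom = segs$chrom[idx], fstart = segs$s[idx] + off)
}

# Format simulated reads as SAM text lines (header + alignments).
.sam_lines <- function(reads, contig_lengths, read_length) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  if (!nrow(reads)) return(header)
  flag <- ifelse(reads$strand == "-", 16L, 0L)
  c(header,
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
            reads$qname, flag, reads$chrom, reads$pos, read_length))
}

#' Simulate IP and input ChIP-Seq libraries with known enrichment
#'
#' Generates single-end 36-bp read libraries for a two-condition
#' contrast over a clustered annotation. Input libraries draw fragment
#' starts uniformly over each cluster locus extended upstream by the
#' fragment margin; IP libraries weight gene-body positions by the
#' gene's condition multiplier from the truth table and leave the rest
#' of the locus at background weight. Strands are Bernoulli(1/2);
#' reverse-strand reads are placed with their 5' end at the fragment's
#' right edge, so the 3'-extended read covers the sampled fragment
#' regardless of strand. Every library contains exactly `depth` reads.
#'
#' Output is one headered SAM file per library (deterministic,
#' byte-identical under a fixed seed), a truth TSV, the counting
#' annotation GTF, a cluster membership TSV and a sample sheet.
#'
#' @param sim Annotation from [simulate_annotation()] (list with
#'   `genes`, `clusters`, `contig_lengths`).
#' @param truth Truth table from [simulate_truth()].
#' @param out_dir Output directory (created if needed).
#' @param depth Reads per library.
#' @param replicates Biological replicates per (condition, role).
#' @param mark Histone-mark label written into the sample sheet.
#' @param read_length,fragment_bp Read geometry (bases).
#' @param seed Integer master seed; each library derives its own
#'   substream.
#' @return The sample sheet `data.frame` (with absolute paths),
#'   invisibly carrying attributes `truth_path`, `annotation_path`,
#'   `membership_path` and `sheet_path`.
#' @export
simulate_libraries <- function(sim, truth, out_dir,
                               depth = 200000, replicates = 2,
                               mark = "H3K9me2", read_length = 36,
                               fragment_bp = 500, seed = 1) {
  stopifnot(depth > 0, replicates >= 1)
  genes <- sim$genes; clusters <- sim$clusters
  contig_lengths <- sim$contig_lengths
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  grid <- expand.grid(replicate = seq_len(replicates),
                      role = c("IP", "input"),
                      condition = 1:2, stringsAsFactors = FALSE)
  grid$library_id <- sprintf("%s_%s_c%d_r%d", mark, grid$role,
                             grid$condition, grid$replicate)
  grid$path <- file.path(out_dir, paste0(grid$library_id, ".sam"))
  mult <- list(
    stats::setNames(truth$multiplier_c1, truth$gene_id),
    stats::setNames(truth$multiplier_c2, truth$gene_id))
  for (i in seq_len(nrow(grid))) {
    reads <- .with_seed(seed * 1000L + i, {
      m <- if (grid$role[i] == "IP") mult[[grid$condition[i]]] else
        stats::setNames(rep(1, length(genes)), genes$gene_id)
      fs <- .sample_fragment_starts(genes, clusters, as.list(m), depth,
                                    fragment_bp)
      strand <- ifelse(runif(depth) < 0.5, "+", "-")
      pos <- ifelse(strand == "+", fs$fstart,
                    fs$fstart + fragment_bp)
      lim <- contig_lengths[as.character(fs$chrom)] - read_length + 1
      pos <- pmax(1L, pmin(as.integer(pos), as.integer(lim)))
      data.frame(qname = sprintf("r%07d", seq_len(depth)),
                 chrom = fs$chrom, pos = pos, strand = strand)
    })
    writeLines(.sam_lines(reads, contig_lengths, read_length),
               grid$path[i])
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  annot_path <- file.path(out_dir, "annotation.gtf")
  write_counting_annotation(genes, clusters, annot_path)
  member_path <- file.path(out_dir, "clusters.tsv")
  membership <- data.frame(cluster_id = genes$cluster_id,
                           gene_id = genes$gene_id)
  utils::write.table(membership, member_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- grid[, c("library_id", "role", "condition", "replicate",
                    "path")]
  sheet$mark <- mark
  sheet <- sheet[, c("library_id", "role", "mark", "condition",
                     "replicate", "path")]
  sheet_path <- file.path(out_dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  attr(sheet, "truth_path") <- truth_path
  attr(sheet, "annotation_path") <- annot_path
  attr(sheet, "membership_path") <- member_path
  attr(sheet, "sheet_path") <- sheet_path
  attr(sheet, "contig_lengths") <- contig_lengths
  sheet
}
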