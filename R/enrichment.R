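#' Input-normalized log2 enrichment contrast for one gene
#'
#' The core statistic: the log2 double ratio
#' \deqn{\log_2\{((CPM^{IP1}+p)/(CPM^{input1}+p)) /
#'              ((CPM^{IP2}+p)/(CPM^{input2}+p))\}}
#' where the IP terms are CPM over the gene body, the input terms CPM
#' over the gene's whole cluster locus (the cluster-local background),
#' and `p` is an optional pseudocount (default 0). Positive values mean
#' enrichment in condition 1 relative to condition 2.
#'
#' With `pseudocount = 0` a zero in any denominator term (either input,
#' or the condition-2 IP) is an error rather than an imputed value: on
#' libraries of realistic depth a cluster-locus background of zero
#' indicates a broken input library, and silently patching it would mask
#' that.
#'
#' @param cpm_ip1,cpm_input1 CPM of the condition-1 IP (gene body) and
#'   input (cluster locus).
#' @param cpm_ip2,cpm_input2 Same for condition 2. All vectorized.
#' @param pseudocount Non-negative value added to all four terms.
#' @param gene_id Optional label(s) used in error messages.
#' @return Numeric vector of log2 fold-changes.
#' @examples
#' contrast_log2fc(300, 200, 150, 200)  # log2(1.5/0.75) = 1
#' @export
contrast_log2fc <- function(cpm_ip1, cpm_input1, cpm_ip2, cpm_input2,
                            pseudocount = 0, gene_id = NULL) {
  stopifnot(pseudocount >= 0)
  vals <- cbind(cpm_ip1, cpm_input1, cpm_ip2, cpm_input2)
  if (any(vals < 0)) stop("CPM values must be non-negative")
  den <- cbind(input1 = cpm_input1 + pseudocount,
               ip2 = cpm_ip2 + pseudocount,
               input2 = cpm_input2 + pseudocount)
  if (any(den == 0)) {
    bad <- which(rowSums(den == 0) > 0)[1L]
    term <- colnames(den)[which(den[bad, ] == 0)[1L]]
    lab <- if (!is.null(gene_id)) paste0(" (gene ", gene_id[bad], ")") else ""
    stop("zero denominator in term '", term, "'", lab,
         " with pseudocount 0; supply a pseudocount or deeper data")
  }
  # computed as a difference of the two per-condition log ratios so that
  # exchanging condition labels negates the result bitwise
  log2((cpm_ip1 + pseudocount) / (cpm_input1 + pseudocount)) -
    log2((cpm_ip2 + pseudocount) / (cpm_input2 + pseudocount))
}

#' Average per-replicate log2 fold-changes
#'
#' The replicate summary is the arithmetic mean of the per-replicate
#' log2 values (averaging after the log, i.e. the log of the geometric
#' mean ratio).
#'
#' @param values Numeric vector of per-replicate log2 fold-changes.
#' @return Their arithmetic mean.
#' @export
average_replicates <- function(values) {
  if (!length(values)) stop("no replicate values to average")
  mean(values)
}

#' Per-gene enrichment contrast and cluster heatmap matrix
#'
#' For each gene carrying a cluster assignment, pairs the four libraries
#' of each replicate index (condition-1 IP and input, condition-2 IP and
#' input, all for `mark`), forms the contrast [contrast_log2fc()] with
#' the IP CPM taken over the gene body and the input CPM over the gene's
#' cluster locus, and averages the per-replicate log2 values. Replicates
#' are paired by their replicate index across the four roles.
#'
#' The heatmap matrix has one row per cluster and one column per paralog
#' group in ascending order — the anterior-to-posterior display
#' direction for collinear clusters. Paralogs absent from a cluster are
#' `NA` (missing, not zero).
#'
#' @param counts `count_table` over the combined gene-body +
#'   cluster-locus annotation (see [count_features()]).
#' @param genes Gene set with `cluster_id` and `paralog_number` filled.
#' @param clusters Cluster loci.
#' @param sheet Sample sheet (see [read_sample_sheet()]) restricted or
#'   not to `mark`; must contain IP and input for both conditions with
#'   equal replicate counts.
#' @param mark Histone-mark label selecting the sheet rows.
#' @param pseudocount Passed to [contrast_log2fc()].
#' @param numerator_condition Which condition is the numerator (1 or 2);
#'   positive values mean enrichment in this condition.
#' @return Object of class `cluster_enrichment`: list with `matrix`
#'   (clusters x paralogs, mean log2FC), `long` (one row per gene:
#'   gene_id, cluster_id, paralog_number, per-replicate values,
#'   mean_log2fc) and `params`.
#' @export
compute_cluster_heatmap <- function(counts, genes, clusters, sheet,
                                    mark, pseudocount = 0,
                                    numerator_condition = 1L) {
  stopifnot(is(counts, "count_table"))
  sh <- sheet[sheet$mark == mark, , drop = FALSE]
  if (!nrow(sh)) stop("sample sheet has no libraries for mark ", mark)
  cond_num <- as.integer(numerator_condition)
  cond_den <- if (cond_num == 1L) 2L else 1L
  lib_for <- function(role, cond) {
    rows <- sh[sh$role == role & sh$condition == cond, , drop = FALSE]
    if (!nrow(rows)) {
      stop("sample sheet is missing ", role, "/condition ", cond,
           " for mark ", mark)
    }
    rows[order(rows$replicate), "library_id"]
  }
  ips1 <- lib_for("IP", cond_num);   ins1 <- lib_for("input", cond_num)
  ips2 <- lib_for("IP", cond_den);   ins2 <- lib_for("input", cond_den)
  nrep <- unique(c(length(ips1), length(ins1), length(ips2), length(ins2)))
  if (length(nrep) != 1L) {
    stop("unequal replicate counts across IP/input and conditions for ",
         mark)
  }
  cpm_mat <- cpm(counts)
  g <- genes[!is.na(genes$cluster_id)]
  if (length(g) < length(genes)) {
    orphan <- setdiff(genes$gene_id, g$gene_id)
    stop("gene(s) without cluster assignment: ",
         paste(orphan, collapse = ", "),
         "; cluster-local background requires a cluster per gene")
  }
  missing_feat <- setdiff(c(g$gene_id, unique(g$cluster_id)),
                          rownames(cpm_mat))
  if (length(missing_feat)) {
    stop("features absent from the count table: ",
         paste(missing_feat, collapse = ", "))
  }
  per_rep <- sapply(seq_len(nrep), function(r) {
    contrast_log2fc(
      cpm_ip1 = cpm_mat[g$gene_id, ips1[r]],
      cpm_input1 = cpm_mat[g$cluster_id, ins1[r]],
      cpm_ip2 = cpm_mat[g$gene_id, ips2[r]],
      cpm_input2 = cpm_mat[g$cluster_id, ins2[r]],
      pseudocount = pseudocount, gene_id = g$gene_id)
  })
  per_rep <- matrix(per_rep, nrow = length(g),
                    dimnames = list(g$gene_id,
                                    paste0("log2fc_rep", seq_len(nrep))))
  long <- data.frame(gene_id = g$gene_id, cluster_id = g$cluster_id,
                     paralog_number = g$paralog_number,
                     per_rep,
                     mean_log2fc = apply(per_rep, 1L, average_replicates),
                     row.names = NULL)
  cl_ids <- names(clusters)
  if (is.null(cl_ids)) cl_ids <- unique(long$cluster_id)
  pmax_n <- max(long$paralog_number, na.rm = TRUE)
  mat <- matrix(NA_real_, nrow = length(cl_ids), ncol = pmax_n,
                dimnames = list(cl_ids, as.character(seq_len(pmax_n))))
  ok <- !is.na(long$paralog_number)
  mat[cbind(long$cluster_id[ok], long$paralog_number[ok])] <-
    long$mean_log2fc[ok]
  structure(list(matrix = mat, long = long,
                 params = list(mark = mark, pseudocount = pseudocount,
                               numerator_condition = cond_num,
                               n_replicates = nrep)),
            class = "cluster_enrichment")
}

#' @export
print.cluster_enrichment <- function(x, ...) {
  cat("cluster_enrichment for mark ", x$params$mark, " (condition ",
      x$params$numerator_condition, " in the numerator; ",
      x$params$n_replicates, " replicate(s))\n", sep = "")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Write enrichment results as TSV
#'
#' Two files: the heatmap matrix (rows clusters, columns paralog groups
#' ascending, `NA` for absent paralogs) and the long form with
#' per-replicate values.
#'
#' @param x A `cluster_enrichment`.
#' @param matrix_path,long_path Output TSV paths.
#' @return Invisibly, `c(matrix_path, long_path)`.
#' @export
write_enrichment <- function(x, matrix_path, long_path) {
  mat <- data.frame(cluster_id = rownames(x$matrix), x$matrix,
                    check.names = FALSE)
  utils::write.table(mat, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, long_path))
}

#' Plot a cluster enrichment heatmap
#'
#' Anterior (paralog 1) to posterior (paralog 13) left to right, one row
#' per cluster, red = enriched in the numerator condition, blue =
#' depleted, on a symmetric scale; missing paralogs are left blank.
#'
#' @param x A `cluster_enrichment`.
#' @param zlim Symmetric color limit; default the max |value|.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.cluster_enrichment <- function(x, zlim = NULL, ...) {
  m <- x$matrix
  if (is.null(zlim)) zlim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(zlim) || zlim == 0) zlim <- 1
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  nr <- nrow(m); nc <- ncol(m)
  graphics::image(x = seq_len(nc), y = seq_len(nr),
                  z = t(m[rev(seq_len(nr)), , drop = FALSE]),
                  zlim = c(-zlim, zlim), col = pal,
                  xlab = "paralog group (anterior → posterior)",
                  ylab = "", axes = FALSE)
  graphics::axis(1, at = seq_len(nc), labels = colnames(m))
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(m)),
                 las = 1)
  graphics::box()
  invisible(x)
}
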