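#' Read a pipeline configuration file
#'
#' Plain YAML key-value file. Recognized keys: `annotation` (GTF path),
#' `cluster_membership` (TSV path, optional when the GTF already carries
#' `cluster_id` attributes), `sample_sheet` (TSV path), `mark`,
#' `pseudocount` (default 0), `extension_3prime_bp` (default 500),
#' `numerator_condition` (default 1), `out_dir`, `seed` (default 1;
#' recorded in the run log — the analysis itself is deterministic).
#' Relative paths are resolved against the config file's directory.
#'
#' @param path Config file path.
#' @return A named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(pseudocount = 0, extension_3prime_bp = 500,
                   numerator_condition = 1L, seed = 1L,
                   cluster_membership = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[k] <- defaults[k]
  }
  need <- c("annotation", "sample_sheet", "mark", "out_dir")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("pipeline config missing keys: ", paste(miss, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (k in c("annotation", "cluster_membership", "sample_sheet")) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]])) {
      cfg[[k]] <- file.path(base, cfg[[k]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the enrichment pipeline end to end
#'
#' Annotation -> alignment loading -> extended-read counting over gene
#' bodies and cluster loci -> CPM -> per-gene log2 enrichment contrast
#' -> replicate averaging -> cluster x paralog heatmap. Writes
#' `heatmap.tsv`, `enrichment_long.tsv`, `counts.tsv` (+ library sizes
#' JSON) and `run_log.json` into `cfg$out_dir`.
#'
#' The run log records every parameter needed to reproduce the run,
#' including the library sizes entering the CPM denominators and the
#' condition placed in the numerator of the contrast (positive log2FC =
#' enriched in that condition).
#'
#' @param cfg A `pipeline_config` (or path to one).
#' @param quiet Suppress progress messages.
#' @return The [compute_cluster_heatmap()] result, invisibly.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  say <- function(...) if (!quiet) message("[clusterchip] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  annot <- stage("annotation", {
    genes <- load_gene_models(cfg$annotation)
    if (!is.null(cfg$cluster_membership)) {
      membership <- read_cluster_membership(cfg$cluster_membership)
    } else if (any(!is.na(genes$cluster_id))) {
      membership <- split(genes$gene_id, genes$cluster_id)
    } else {
      membership <- infer_cluster_membership(genes)
    }
    clusters <- build_cluster_loci(genes, membership)
    list(genes = attr(clusters, "genes"), clusters = clusters)
  })
  say(length(annot$genes), " genes, ", length(annot$clusters),
      " cluster loci")
  sheet <- stage("sample_sheet", read_sample_sheet(cfg$sample_sheet))
  sheet_mark <- sheet[sheet$mark == cfg$mark, , drop = FALSE]
  if (!nrow(sheet_mark)) {
    stop("stage 'sample_sheet': no libraries for mark ", cfg$mark,
         call. = FALSE)
  }
  for (cond in 1:2) for (role in c("IP", "input")) {
    if (!any(sheet_mark$role == role & sheet_mark$condition == cond)) {
      stop("stage 'sample_sheet': missing ", role, "/condition ", cond,
           " for mark ", cfg$mark, call. = FALSE)
    }
  }
  libs <- stage("alignments", load_libraries(sheet_mark))
  say("loaded ", length(libs), " libraries; sizes: ",
      paste(vapply(libs, function(x) x$library_size, 0), collapse = ", "))
  feats <- .combine_features(annot$genes, annot$clusters)
  ctab <- stage("counting", count_features(
    libs, feats, counting_config(cfg$extension_3prime_bp)))
  enr <- stage("enrichment", compute_cluster_heatmap(
    ctab, annot$genes, annot$clusters, sheet_mark, mark = cfg$mark,
    pseudocount = cfg$pseudocount,
    numerator_condition = cfg$numerator_condition))
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
  }
  write_enrichment(enr, file.path(cfg$out_dir, "heatmap.tsv"),
                   file.path(cfg$out_dir, "enrichment_long.tsv"))
  write_count_table(ctab, file.path(cfg$out_dir, "counts.tsv"))
  log <- list(
    parameters = list(
      annotation = cfg$annotation,
      cluster_membership = cfg$cluster_membership,
      sample_sheet = cfg$sample_sheet, mark = cfg$mark,
      pseudocount = cfg$pseudocount,
      extension_3prime_bp = cfg$extension_3prime_bp,
      numerator_condition = cfg$numerator_condition, seed = cfg$seed),
    condition_mapping = paste0(
      "positive log2FC = enriched in condition ",
      cfg$numerator_condition),
    library_sizes = as.list(ctab$library_sizes),
    n_genes = length(annot$genes),
    n_clusters = length(annot$clusters))
  jsonlite::write_json(log, file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("condition ", cfg$numerator_condition, " in the numerator; ",
      "outputs in ", cfg$out_dir)
  invisible(enr)
}
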