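#' Counting configuration
#'
#' Defaults reproduce the broad-mark counting convention: reads extended
#' 500 bp at the 3' end, multimapping reads counted at every reported
#' location, reads overlapping several features counted once per feature
#' (multi-overlap), strand ignored.
#'
#' @param extension_3prime_bp 3' extension in bases (>= 0).
#' @param count_multimappers Kept for the record; multimapper retention
#'   is enforced at load time ([load_alignments()] keeps secondary
#'   records).
#' @param count_multi_overlap Logical; `FALSE` is not supported in this
#'   version (integer multi-overlap counting is the contract).
#' @param strandedness `"unstranded"` only.
#' @return A list of class `counting_config`.
#' @export
counting_config <- function(extension_3prime_bp = 500,
                            count_multimappers = TRUE,
                            count_multi_overlap = TRUE,
                            strandedness = "unstranded") {
  stopifnot(extension_3prime_bp >= 0,
            isTRUE(count_multi_overlap),
            strandedness == "unstranded")
  structure(list(extension_3prime_bp = extension_3prime_bp,
                 count_multimappers = count_multimappers,
                 count_multi_overlap = count_multi_overlap,
                 strandedness = strandedness),
            class = "counting_config")
}

#' Count extended reads over features
#'
#' Each retained alignment record is extended at its 3' end by
#' `cfg$extension_3prime_bp` and then increments every feature it
#' overlaps by at least one base, irrespective of strand. Features may
#' overlap each other (gene bodies nested in their cluster locus are the
#' typical case); a read then counts once in each.
#'
#' Reads on contigs absent from the feature annotation contribute to the
#' library size but to no feature; a warning names the orphan contigs.
#'
#' @param libraries Named list of `alignment_set` (see
#'   [load_libraries()]), or a single `alignment_set`.
#' @param features `GRanges` with `feature_id` and `feature_class`
#'   metadata columns (see [write_counting_annotation()] /
#'   `clusterchip:::.combine_features`), or a plain gene set, in which
#'   case all records are class `gene_body`.
#' @param cfg A [counting_config()].
#' @return A `count_table`: list with `counts` (integer matrix, features
#'   x libraries, zeros explicit), `feature_class` (character vector
#'   along rows) and `library_sizes` (named numeric along columns).
#' @export
count_features <- function(libraries, features, cfg = counting_config()) {
  if (is(libraries, "alignment_set")) {
    libraries <- stats::setNames(list(libraries), libraries$library_id)
  }
  if (is.null(features$feature_id)) {
    features <- .combine_features(features, GRanges())
  }
  fid <- features$feature_id
  counts <- matrix(0L, nrow = length(features), ncol = length(libraries),
                   dimnames = list(fid, names(libraries)))
  sizes <- stats::setNames(numeric(length(libraries)), names(libraries))
  feat_chroms <- unique(as.character(seqnames(features)))
  for (j in seq_along(libraries)) {
    lib <- libraries[[j]]
    sizes[j] <- lib$library_size
    if (!lib$library_size) next
    ext <- extend_reads(lib$reads, "extend_by", cfg$extension_3prime_bp)
    orphan <- setdiff(unique(as.character(seqnames(ext))), feat_chroms)
    if (length(orphan)) {
      warning("library ", names(libraries)[j], ": reads on contigs ",
              "absent from the annotation get zero counts: ",
              paste(orphan, collapse = ", "))
    }
    # seqlevel-mismatch warnings are redundant with the orphan message
    counts[, j] <- suppressWarnings(
      countOverlaps(features, ext, ignore.strand = TRUE,
                    minoverlap = 1L))
  }
  structure(list(counts = counts,
                 feature_class = stats::setNames(
                   as.character(features$feature_class), fid),
                 library_sizes = sizes),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table: ", nrow(x$counts), " features (",
      sum(x$feature_class == "gene_body"), " gene bodies, ",
      sum(x$feature_class == "cluster_locus"), " cluster loci) x ",
      ncol(x$counts), " libraries\n", sep = "")
  invisible(x)
}

#' Convert a count table to counts per million mapped reads
#'
#' `cpm = count * 1e6 / library_size`, where the library size is the
#' retained-record count of the library (not the sum of feature counts,
#' which double-counts multi-overlap features).
#'
#' @param table A `count_table` from [count_features()].
#' @return Numeric matrix with the dimensions of `table$counts`.
#' @export
cpm <- function(table) {
  stopifnot(is(table, "count_table"))
  sizes <- table$library_sizes
  zero <- sizes == 0
  if (any(zero)) {
    stop("library_size is zero for: ",
         paste(names(sizes)[zero], collapse = ", "))
  }
  sweep(table$counts, 2L, sizes, function(cnt, n) cnt * 1e6 / n)
}

#' Write a count table as TSV (+ sidecar library-size JSON)
#'
#' @param table A `count_table`.
#' @param path Output TSV; the library sizes go to `<path>.sizes.json`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  long <- data.frame(
    feature_id = rep(rownames(table$counts), ncol(table$counts)),
    feature_class = rep(unname(table$feature_class), ncol(table$counts)),
    library_id = rep(colnames(table$counts), each = nrow(table$counts)),
    count = as.vector(table$counts))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(table$library_sizes),
                       paste0(path, ".sizes.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
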