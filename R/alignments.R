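#' Read a sample sheet
#'
#' The sample sheet declares the identity of each sequencing library:
#' columns `library_id`, `role` (`IP` or `input`), `mark` (e.g.
#' `H3K9me2`), `condition` (1 or 2), `replicate` (integer >= 1) and
#' `path` (SAM/BAM file). The combination (role, mark, condition,
#' replicate) must be unique.
#'
#' @param path TSV path.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved; default the sheet's own directory.
#' @return A `data.frame` with the validated columns.
#' @export
read_sample_sheet <- function(path, base_dir = dirname(path)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("library_id", "role", "mark", "condition", "replicate", "path")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  df$condition <- as.integer(df$condition)
  df$replicate <- as.integer(df$replicate)
  if (!all(df$role %in% c("IP", "input"))) {
    stop("role must be 'IP' or 'input'")
  }
  key <- paste(df$role, df$mark, df$condition, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (role, mark, condition, replicate): ",
         key[duplicated(key)][1L])
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(base_dir, df$path[rel])
  df
}

#' Load a SAM/BAM alignment file under the package filtering contract
#'
#' Retains mapped primary and secondary alignments (secondary records
#' kept so multimapping reads contribute to every reported location, the
#' `-M` counting convention); drops unmapped and supplementary records.
#' No MAPQ filter and no duplicate removal are applied. Paired-end
#' records are rejected outright: the counting and extension semantics
#' here are defined for single-end libraries only, and silently
#' half-counting pairs would corrupt the CPM denominator.
#'
#' The library size used as the CPM denominator is the retained record
#' count from this same filter, for gene-body and cluster-locus counts
#' alike.
#'
#' @param path SAM or BAM file. SAM is converted on the fly via
#'   [Rsamtools::asBam()].
#' @param library_id Optional label stored on the result.
#' @return An object of class `alignment_set`: list with `reads` (a
#'   `GRanges`, one range per retained record, width = read length,
#'   stranded), `library_size` (retained count) and `library_id`.
#' @export
load_alignments <- function(path, library_id = basename(path)) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "qwidth", "strand"))
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- res$flag
  if (any(bitwAnd(flag, 1L) != 0L)) {
    stop("paired-end records present in ", path,
         "; only single-end libraries are supported")
  }
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 2048L) == 0L
  n <- sum(keep)
  if (n) {
    reads <- GRanges(as.character(res$rname[keep]),
                     IRanges(res$pos[keep], width = res$qwidth[keep]),
                     strand = res$strand[keep],
                     qname = res$qname[keep])
  } else {
    reads <- GRanges()
    mcols(reads) <- DataFrame(qname = character())
  }
  structure(list(reads = reads, library_size = n, library_id = library_id),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set '", x$library_id, "': ", x$library_size,
      " retained records\n", sep = "")
  invisible(x)
}

#' Load every library of a sample sheet
#'
#' @param sheet Data frame from [read_sample_sheet()].
#' @return Named list of `alignment_set`, one per row, named by
#'   `library_id`.
#' @export
load_libraries <- function(sheet) {
  out <- lapply(seq_len(nrow(sheet)), function(i) {
    load_alignments(sheet$path[i], library_id = sheet$library_id[i])
  })
  stats::setNames(out, sheet$library_id)
}

#' Extend aligned reads for counting or coverage
#'
#' Two extension modes mirror the two track/counting conventions for
#' ChIP fragments sequenced from one end:
#' \describe{
#'   \item{`extend_by`}{lengthen each read by `bp` at its 3' end in read
#'     orientation (total length `read_length + bp`) — the counting
#'     convention (3' extension 500 bp by default elsewhere in the
#'     package).}
#'   \item{`extend_to`}{set each read to length `max(bp, read_length)`
#'     anchored at its 5' end — the coverage-track convention
#'     (fragment-size extension).}
#' }
#' Reverse-strand reads extend leftwards; extensions are clamped at
#' position 1 (and at the contig length when `seqlengths` are set) so
#' degenerate placements never yield out-of-bounds coordinates.
#'
#' @param reads `GRanges` of reads (stranded), or an `alignment_set`.
#' @param mode `"extend_by"` or `"extend_to"`.
#' @param bp Extension length in bases, >= 0.
#' @return A `GRanges` of extended intervals.
#' @examples
#' r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, width = 36),
#'                             strand = "+")
#' extend_reads(r, "extend_by", 500)  # 1000-1535
#' @export
extend_reads <- function(reads, mode = c("extend_by", "extend_to"), bp) {
  mode <- match.arg(mode)
  if (is(reads, "alignment_set")) reads <- reads$reads
  stopifnot(bp >= 0)
  if (!length(reads)) return(granges(reads))
  w <- width(reads)
  new_w <- switch(mode,
                  extend_by = w + bp,
                  extend_to = pmax(bp, w))
  out <- resize(granges(reads), new_w, fix = "start")
  # clamp below 1 without requiring seqlengths
  neg <- start(out) < 1L
  if (any(neg)) start(out)[neg] <- 1L
  if (!all(is.na(seqlengths(out)))) out <- trim(out)
  out
}
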