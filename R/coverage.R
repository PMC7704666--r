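#' Coverage-track configuration
#'
#' Defaults mirror the broad-mark ChIP track convention: 50-bp bins,
#' reads extended to the 500-bp fragment size, CPM normalization. For
#' RNA-style tracks use `bin_size = 1`, `extend_to_bp = 0`.
#'
#' @param bin_size Bin width in bases (>= 1).
#' @param extend_to_bp Fragment length each read is extended to from its
#'   5' end (0 = no extension).
#' @param normalization Only `"CPM"` is supported.
#' @return A list of class `coverage_config`.
#' @export
coverage_config <- function(bin_size = 50, extend_to_bp = 500,
                            normalization = "CPM") {
  stopifnot(bin_size >= 1, extend_to_bp >= 0, normalization == "CPM")
  structure(list(bin_size = as.integer(bin_size),
                 extend_to_bp = as.integer(extend_to_bp),
                 normalization = normalization),
            class = "coverage_config")
}

#' Binned CPM coverage track
#'
#' Tiles each contig from its first base in steps of `cfg$bin_size`
#' (the last bin truncated at the contig end) and assigns each bin the
#' number of extended reads overlapping it, scaled to counts per million
#' mapped reads: `value = overlapping_reads * 1e6 / library_size`. A
#' read spanning a bin boundary counts once in each bin it touches, so a
#' bin's value never exceeds 1e6 and, when every read lies wholly inside
#' a single bin, the track mass totals exactly 1e6.
#'
#' @param aln An `alignment_set` with at least one retained record.
#' @param cfg A [coverage_config()].
#' @param contig_lengths Named numeric vector of contig lengths covering
#'   every contig with reads.
#' @return A `GRanges` of bins with a numeric `score` column (class
#'   `coverage_track`); zero bins are retained in the object and dropped
#'   only on bedGraph export.
#' @export
binned_cpm_track <- function(aln, cfg = coverage_config(),
                             contig_lengths) {
  stopifnot(is(aln, "alignment_set"))
  if (aln$library_size == 0) stop("empty library: ", aln$library_id)
  have <- unique(as.character(seqnames(aln$reads)))
  missing <- setdiff(have, names(contig_lengths))
  if (length(missing)) {
    stop("contig_lengths missing for: ", paste(missing, collapse = ", "))
  }
  ext <- extend_reads(aln, "extend_to", cfg$extend_to_bp)
  bins <- lapply(names(contig_lengths), function(chrom) {
    len <- contig_lengths[[chrom]]
    starts <- seq(1L, len, by = cfg$bin_size)
    GRanges(chrom, IRanges(starts,
                           end = pmin(starts + cfg$bin_size - 1L, len)))
  })
  bins <- suppressWarnings(do.call(c, bins))
  seqlengths(bins) <- contig_lengths[seqlevels(bins)]
  hits <- countOverlaps(bins, ext, ignore.strand = TRUE)
  bins$score <- hits * 1e6 / aln$library_size
  attr(bins, "library_id") <- aln$library_id
  bins
}

#' Write a coverage track as bedGraph
#'
#' Four-column bedGraph, 0-based half-open; zero-valued bins are omitted
#' (the sparse convention).
#'
#' @param track `GRanges` with a `score` column from
#'   [binned_cpm_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  nz <- track[track$score != 0]
  rtracklayer::export(nz, path, format = "bedGraph")
  invisible(path)
}
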