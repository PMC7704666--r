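#' Parse a browser-style region string
#'
#' Converts text coordinates such as `"chr6:52155590-52260880"` (1-based,
#' inclusive, the UCSC browser convention) into a [GenomicRanges::GRanges]
#' of length one. The inverse of [format_region()]; the two round-trip
#' exactly.
#'
#' @param x Character vector of `"chrom:start-end"` strings.
#' @return A `GRanges` with one range per input string, unstranded.
#' @examples
#' parse_region("chr6:52155590-52260880")
#' @export
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) {
    stop("malformed region string: ", paste(x[bad], collapse = ", "))
  }
  chrom <- vapply(m, `[[`, "", 2L)
  s <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 3L)))
  e <- as.numeric(gsub(",", "", vapply(m, `[[`, "", 4L)))
  if (any(s > e)) stop("region start exceeds end: ", x[s > e][1L])
  GRanges(chrom, IRanges(s, e))
}

#' Format genomic ranges as region strings
#'
#' @param gr A `GRanges`.
#' @return Character vector `"chrom:start-end"`, 1-based inclusive.
#' @seealso [parse_region()]
#' @export
format_region <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr), end(gr))
}

# Validate/normalize a gene-model GRanges: required mcols with types.
.as_gene_set <- function(gr) {
  mc <- mcols(gr)
  if (is.null(mc$gene_id)) stop("gene models require a gene_id column")
  if (anyDuplicated(mc$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(mc$gene_id[duplicated(mc$gene_id)]), collapse = ", "))
  }
  if (is.null(mc$gene_name)) mc$gene_name <- mc$gene_id
  if (is.null(mc$cluster_id)) mc$cluster_id <- NA_character_
  if (is.null(mc$paralog_number)) mc$paralog_number <- NA_integer_
  mc$paralog_number <- as.integer(mc$paralog_number)
  if (any(!is.na(mc$paralog_number) & mc$paralog_number < 1L)) {
    stop("paralog_number must be >= 1")
  }
  mcols(gr) <- mc[, c("gene_id", "gene_name", "cluster_id", "paralog_number")]
  names(gr) <- mc$gene_id
  gr
}

# GTF lines must have 9 tab-separated fields; report the first offender
# with its line number (rtracklayer's own message lacks one).
.check_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9L)) {
    ln <- which(body)[which(nf < 9L)[1L]]
    stop("malformed GTF line ", ln, " in ", path,
         " (expected 9 tab-separated fields, got ", nf[nf < 9L][1L], ")")
  }
  invisible(TRUE)
}

# comment-only/empty GTFs trip rtracklayer's format sniffing
.gtf_is_empty <- function(path) {
  lines <- readLines(path, warn = FALSE)
  !any(!grepl("^#", lines) & nzchar(lines))
}

#' Load gene models from GTF or BED
#'
#' Reads gene-level records into a gene set: a `GRanges` carrying
#' `gene_id`, `gene_name`, `cluster_id` and `paralog_number` metadata
#' columns. GTF coordinates are 1-based inclusive (GENCODE dialect);
#' BED is 0-based half-open; both are converted by rtracklayer to the
#' 1-based closed convention of `GRanges`.
#'
#' For GTF input only records with feature type `gene` are kept (files
#' written by [write_counting_annotation()] mark cluster-locus records
#' with `feature_class "cluster_locus"`; those are excluded here and
#' recovered via their members). Duplicated `gene_id`s are an error.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed"`; guessed from the file extension by
#'   default.
#' @return A `GRanges` gene set (possibly empty), named by `gene_id`.
#' @export
load_gene_models <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gtf"
  }
  if (format == "gtf") {
    .check_gtf_lines(path)
    if (.gtf_is_empty(path)) {
      gr <- GRanges()
    } else {
      gr <- rtracklayer::import(path, format = "gtf")
    }
    if (length(gr)) {
      keep <- as.character(gr$type) == "gene"
      if (!is.null(gr$feature_class)) {
        keep <- keep & (is.na(gr$feature_class) |
                          gr$feature_class != "cluster_locus")
      }
      gr <- gr[keep]
      if (length(gr) && is.null(gr$gene_id)) {
        stop("GTF gene records lack a gene_id attribute: ", path)
      }
    }
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    mcols(gr) <- DataFrame(gene_id = if (length(gr)) gr$name else character())
  }
  if (!length(gr)) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_id = character(), gene_name = character(),
                           cluster_id = character(),
                           paralog_number = integer())
    return(gr)
  }
  .as_gene_set(granges(gr, use.mcols = TRUE))
}

#' Read cluster membership from a two-column TSV
#'
#' @param path TSV with columns `cluster_id`, `gene_id` (header optional
#'   but recommended).
#' @return A named list mapping `cluster_id` to character vectors of
#'   `gene_id`s.
#' @export
read_cluster_membership <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("cluster_id", "gene_id") %in% names(df))) {
    stop("membership TSV needs columns cluster_id and gene_id: ", path)
  }
  split(df$gene_id, df$cluster_id)
}

#' Infer cluster membership from gene-name prefixes
#'
#' Convenience for nomenclatures like the mouse Hox genes, where the
#' cluster is implicit in the name (`Hoxa1` belongs to cluster `Hoxa`).
#'
#' @param genes A gene set from [load_gene_models()].
#' @param pattern Regex whose first capture group is the cluster id;
#'   default captures an alphabetic prefix before a trailing number.
#' @return Named list `cluster_id -> gene_ids`; genes whose name does not
#'   match are omitted.
#' @export
infer_cluster_membership <- function(genes,
                                     pattern = "^([A-Za-z]+)[0-9]+$") {
  nm <- genes$gene_name
  hit <- grepl(pattern, nm)
  cl <- sub(pattern, "\\1", nm[hit])
  split(genes$gene_id[hit], cl)
}

#' Assemble cluster loci from member genes
#'
#' A cluster locus is the genomic span from the first member gene to the
#' last: `[min(start), max(end)]` over the members, all of which must lie
#' on one chromosome. Member order within the locus is ascending genomic
#' start (the anterior-to-posterior direction for a 3'-to-5' collinear
#' cluster on the plus strand).
#'
#' @param genes Gene set (`GRanges` with `gene_id`).
#' @param membership Named list `cluster_id -> gene_ids`, e.g. from
#'   [read_cluster_membership()] or [infer_cluster_membership()].
#' @param annotate When `TRUE` (default), the returned gene set in
#'   attribute is ignored; membership is also written back onto a copy of
#'   `genes` retrievable via `attr(, "genes")`.
#' @return A `GRanges` of cluster loci with metadata columns `cluster_id`
#'   and `members` (a `CharacterList` ordered by genomic start), plus an
#'   attribute `"genes"`: `genes` with `cluster_id` filled in.
#' @export
build_cluster_loci <- function(genes, membership, annotate = TRUE) {
  if (!length(membership)) stop("empty cluster membership")
  known <- genes$gene_id
  loci <- lapply(names(membership), function(cid) {
    ids <- membership[[cid]]
    if (!length(ids)) stop("cluster ", cid, " has no members")
    missing <- setdiff(ids, known)
    if (length(missing)) {
      stop("cluster ", cid, " references unknown gene_id: ",
           paste(missing, collapse = ", "))
    }
    g <- genes[match(ids, known)]
    chroms <- unique(as.character(seqnames(g)))
    if (length(chroms) != 1L) {
      stop("cluster ", cid, " spans multiple chromosomes: ",
           paste(chroms, collapse = ", "))
    }
    g <- g[order(start(g))]
    out <- GRanges(chroms, IRanges(min(start(g)), max(end(g))))
    mcols(out) <- DataFrame(cluster_id = cid,
                            members = I(list(g$gene_id)))
    out
  })
  loci <- suppressWarnings(do.call(c, loci))
  names(loci) <- loci$cluster_id
  if (annotate) {
    for (cid in names(membership)) {
      genes$cluster_id[genes$gene_id %in% membership[[cid]]] <- cid
    }
    attr(loci, "genes") <- genes
  }
  loci
}

#' Write the combined counting annotation
#'
#' Emits a GTF with one `gene_body` record per gene and one
#' `cluster_locus` record per cluster, distinguished by a
#' `feature_class` attribute. This is the single annotation against
#' which both the gene-body IP counts and the cluster-locus input
#' background counts are obtained, so one counting pass serves both.
#' The file reloads losslessly through [load_gene_models()] (gene
#' records) and [load_counting_annotation()] (both classes).
#'
#' @param genes Gene set.
#' @param clusters Cluster loci from [build_cluster_loci()].
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_counting_annotation <- function(genes, clusters, path) {
  feats <- .combine_features(genes, clusters)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#!clusterchip counting annotation",
               "#!feature_class: gene_body | cluster_locus"), con)
  if (length(feats)) {
    mc <- mcols(feats)
    attrs <- sprintf('gene_id "%s"; feature_class "%s";',
                     mc$feature_id, mc$feature_class)
    extra <- ifelse(is.na(mc$gene_name), "",
                    sprintf(' gene_name "%s";', mc$gene_name))
    extra2 <- ifelse(is.na(mc$cluster_id), "",
                     sprintf(' cluster_id "%s";', mc$cluster_id))
    extra3 <- ifelse(is.na(mc$paralog_number), "",
                     sprintf(' paralog_number "%d";', mc$paralog_number))
    writeLines(sprintf("%s\tclusterchip\tgene\t%d\t%d\t.\t%s\t.\t%s%s%s%s",
                       as.character(seqnames(feats)), start(feats),
                       end(feats), as.character(strand(feats)),
                       attrs, extra, extra2, extra3),
               con)
  }
  invisible(path)
}

#' Reload a counting annotation written by [write_counting_annotation()]
#'
#' @param path GTF path.
#' @return List with elements `genes` (gene set) and `clusters`
#'   (cluster loci rebuilt from membership implied by `cluster_id`).
#' @export
load_counting_annotation <- function(path) {
  .check_gtf_lines(path)
  gr <- if (.gtf_is_empty(path)) GRanges() else
    rtracklayer::import(path, format = "gtf")
  if (!length(gr)) {
    genes <- load_gene_models(path)  # canonical empty gene set
    return(list(genes = genes, clusters = GRanges()))
  }
  cls <- gr$feature_class
  genes <- .as_gene_set(granges(gr[cls == "gene_body"], use.mcols = TRUE))
  membership <- split(genes$gene_id, genes$cluster_id)
  clusters <- if (length(membership)) {
    build_cluster_loci(genes, membership, annotate = FALSE)
  } else GRanges()
  list(genes = genes, clusters = clusters)
}

# Stack genes and clusters into one feature GRanges for counting.
.combine_features <- function(genes, clusters) {
  n_g <- length(genes); n_c <- length(clusters)
  if (n_g + n_c == 0L) {
    out <- GRanges()
    mcols(out) <- DataFrame(feature_id = character(),
                            feature_class = character(),
                            gene_name = character(),
                            cluster_id = character(),
                            paralog_number = integer())
    return(out)
  }
  gg <- granges(genes)
  mcols(gg) <- DataFrame(
    feature_id = genes$gene_id,
    feature_class = rep("gene_body", n_g),
    gene_name = genes$gene_name,
    cluster_id = genes$cluster_id,
    paralog_number = genes$paralog_number)
  cc <- granges(clusters)
  if (n_c) {
    mcols(cc) <- DataFrame(
      feature_id = clusters$cluster_id,
      feature_class = rep("cluster_locus", n_c),
      gene_name = NA_character_,
      cluster_id = clusters$cluster_id,
      paralog_number = NA_integer_)
  } else {
    mcols(cc) <- mcols(gg)[0, ]
  }
  out <- suppressWarnings(c(gg, cc))
  names(out) <- out$feature_id
  out
}

#' The bundled mouse Hox annotation fixture
#'
#' The standard mouse Hox complement: 39 genes in four clusters (Hoxa,
#' Hoxb, Hoxc, Hoxd; paralog groups 1-13), with the cluster boundaries
#' at their mm10 coordinates (`chr6:52155590-52260880`,
#' `chr11:96194316-96368256`, `chr15:102921103-103036852`,
#' `chr2:74668310-74765142`). Gene placement inside each cluster is
#' synthetic: members are spaced evenly in ascending paralog order with
#' the first gene's start and the last gene's end pinned to the cluster
#' boundaries, so the loci rebuilt from the members reproduce the
#' boundary coordinates exactly. Suitable as a deterministic test and
#' demonstration annotation, not as a real gene model.
#'
#' @return List with `genes` (39-gene set) and `clusters` (4 loci).
#' @examples
#' hox <- hox_fixture()
#' format_region(hox$clusters)
#' @export
hox_fixture <- function() {
  complement <- list(
    Hoxa = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 9L, 10L, 11L, 13L),
    Hoxb = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 13L),
    Hoxc = c(4L, 5L, 6L, 8L, 9L, 10L, 11L, 12L, 13L),
    Hoxd = c(1L, 3L, 4L, 8L, 9L, 10L, 11L, 12L, 13L))
  bounds <- c(Hoxa = "chr6:52155590-52260880",
              Hoxb = "chr11:96194316-96368256",
              Hoxc = "chr15:102921103-103036852",
              Hoxd = "chr2:74668310-74765142")
  genes <- lapply(names(complement), function(cl) {
    par <- complement[[cl]]
    n <- length(par)
    span <- parse_region(bounds[[cl]])
    s <- start(span); e <- end(span)
    len <- floor((e - s + 1) / (2 * n))
    starts <- round(seq(s, e - len + 1, length.out = n))
    gr <- GRanges(seqnames(span), IRanges(starts, width = len))
    # pin the locus boundaries exactly
    end(gr)[n] <- e
    mcols(gr) <- DataFrame(
      gene_id = paste0(cl, par), gene_name = paste0(cl, par),
      cluster_id = cl, paralog_number = par)
    gr
  })
  genes <- .as_gene_set(suppressWarnings(do.call(c, genes)))
  membership <- split(genes$gene_id, genes$cluster_id)
  clusters <- build_cluster_loci(genes, membership, annotate = FALSE)
  clusters <- clusters[names(complement)]
  list(genes = genes, clusters = clusters)
}
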