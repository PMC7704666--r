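#' ChIP-qPCR enrichment as percent of input
#'
#' Expresses IP signal as a percentage of the input signal, correcting
#' the input for the fraction of chromatin it represents. Two
#' equivalent measurement modes:
#' \describe{
#'   \item{quantity}{`100 * q_ip / (q_input / f)` with absolute
#'     quantities from a standard curve;}
#'   \item{ct}{`100 * 2^((ct_input - log2(1/f)) - ct_ip)` with raw
#'     threshold cycles, i.e. the input Ct adjusted to 100% of
#'     chromatin before the delta.}
#' }
#' The two agree exactly when `q = 2^(-ct)` (ideal amplification
#' efficiency).
#'
#' `input_fraction` is the fraction of chromatin the input sample
#' represents relative to the IP. It defaults to 1 (no correction)
#' because published percent-of-input values often leave the dilution
#' implicit; for a protocol saving 0.3 ml of a 10.3-ml lysate as input
#' against 10 ml for IP, the fraction is 0.3/10 = 0.03.
#'
#' @param q_ip,q_input Quantities (quantity mode), > 0 for input.
#' @param ct_ip,ct_input Threshold cycles (ct mode).
#' @param input_fraction `f` in (0, 1].
#' @param mode `"quantity"` or `"ct"`; inferred from which arguments are
#'   supplied when omitted.
#' @return Percent of input (vectorized).
#' @examples
#' percent_input(q_ip = 5, q_input = 20, input_fraction = 0.25)  # 6.25
#' percent_input(ct_ip = 20, ct_input = 18, input_fraction = 0.25)
#' @export
percent_input <- function(q_ip = NULL, q_input = NULL,
                          ct_ip = NULL, ct_input = NULL,
                          input_fraction = 1,
                          mode = c("auto", "quantity", "ct")) {
  mode <- match.arg(mode)
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  if (mode == "auto") {
    mode <- if (!is.null(q_ip)) "quantity" else "ct"
  }
  if (mode == "quantity") {
    if (is.null(q_ip) || is.null(q_input)) {
      stop("quantity mode needs q_ip and q_input")
    }
    if (any(q_input <= 0)) stop("q_input must be > 0")
    100 * q_ip / (q_input / input_fraction)
  } else {
    if (is.null(ct_ip) || is.null(ct_input)) {
      stop("ct mode needs ct_ip and ct_input")
    }
    100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
  }
}

#' Filter differential-expression records
#'
#' Keeps genes satisfying both published criteria, with strict
#' inequalities: adjusted p-value strictly below `padj_max` AND
#' expression strictly above `tpm_min` in either or both groups.
#' Records with missing `padj` (e.g. genes DESeq2 filtered out) are
#' dropped.
#'
#' @param records Data frame with columns `gene_id`, `padj`, `tpm_a`,
#'   `tpm_b`.
#' @param padj_max Adjusted p-value threshold (default 0.05).
#' @param tpm_min TPM threshold (default 1).
#' @return The surviving subset, same columns.
#' @export
filter_differential_genes <- function(records, padj_max = 0.05,
                                      tpm_min = 1) {
  need <- c("gene_id", "padj", "tpm_a", "tpm_b")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  keep <- !is.na(records$padj) & records$padj < padj_max &
    (records$tpm_a > tpm_min | records$tpm_b > tpm_min)
  records[keep, , drop = FALSE]
}
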