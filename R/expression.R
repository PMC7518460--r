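#' Read a per-transcript abundance table
#'
#' Accepts the RSEM `.isoforms.results` dialect (tab-separated, header row)
#' or any TSV with at least `transcript_id`, `effective_length` and
#' `expected_count` columns; a `TPM` column is optional.
#'
#' @param path Path to the TSV.
#' @return A data.frame with the columns above.
#' @export
read_abundance <- function(path) {
  ab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("transcript_id", "effective_length", "expected_count")
  if (!all(need %in% names(ab)))
    stop("abundance table must have columns: ", paste(need, collapse = ", "))
  ab
}

#' Compute TPM from expected counts and effective lengths
#'
#' TPM for transcript *i* is `1e6 * (c_i/l_i) / sum_j(c_j/l_j)` where `c` is
#' the expected count and `l` the effective length in nucleotides, so TPM
#' always sums to one million over the table and is invariant to uniform
#' rescaling of the counts.
#'
#' @param records Data.frame with columns `transcript_id`,
#'   `effective_length`, `expected_count` and optionally `TPM`.
#' @param use_input_tpm If `TRUE` and a `TPM` column is present, pass it
#'   through instead of recomputing. Default recompute.
#' @return The input data.frame with a `tpm` column appended (row order
#'   preserved).
#' @export
compute_tpm <- function(records, use_input_tpm = FALSE) {
  stopifnot(is.data.frame(records))
  l <- records$effective_length
  c_ <- records$expected_count
  if (any(!is.finite(l)) || any(l <= 0))
    stop("all effective lengths must be positive")
  if (any(!is.finite(c_)) || any(c_ < 0))
    stop("expected counts must be non-negative")
  if (use_input_tpm && "TPM" %in% names(records)) {
    records$tpm <- records$TPM
    return(records)
  }
  if (all(c_ == 0))
    stop("degenerate input: all expected counts are zero")
  rate <- c_ / l
  records$tpm <- 1e6 * rate / sum(rate)
  records
}

#' Natural log of TPM
#'
#' Zero-TPM transcripts have no defined log expression and are excluded
#' from clustering rather than pseudocounted; they are returned as `NA`
#' here and reported in a side list by the pipeline.
#'
#' @param tpm Numeric vector of non-negative TPM values.
#' @return `log(tpm)`, with `NA_real_` where `tpm == 0`.
#' @export
ln_tpm <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM must be non-negative")
  out <- rep(NA_real_, length(tpm))
  pos <- !is.na(tpm) & tpm > 0
  out[pos] <- log(tpm[pos])
  out
}
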