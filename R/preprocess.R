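#' Log-transform TPM values
#'
#' Elementwise `log2(x + 1)` of a non-negative TPM matrix (or vector).
#'
#' @param tpm Non-negative numeric matrix or vector.
#' @return Object of the same shape on the log2(TPM + 1) scale.
#' @export
#' @examples
#' tpm_log_transform(c(0, 1, 7))  # 0, 1, 3
tpm_log_transform <- function(tpm) {
  if (!is.numeric(tpm)) abort("`tpm` must be numeric.")
  if (any(tpm < 0, na.rm = TRUE)) {
    abort("TPM values must be non-negative.")
  }
  log2(tpm + 1)
}

#' Drop genes that are mostly zero
#'
#' Removes genes whose fraction of exactly-zero entries is strictly greater
#' than `zero_fraction` (default: zero in more than 70% of samples). Gene
#' order among survivors is preserved, and the filter is idempotent.
#'
#' @param cohort An [expression_cohort()].
#' @param zero_fraction Threshold in (0, 1); strict `>` comparison.
#' @return The filtered `expression_cohort`.
#' @export
filter_low_expression <- function(cohort, zero_fraction = 0.7) {
  stopifnot(is.numeric(zero_fraction), length(zero_fraction) == 1)
  if (zero_fraction <= 0 || zero_fraction >= 1) {
    abort("`zero_fraction` must lie strictly between 0 and 1.")
  }
  frac0 <- rowMeans(cohort$values == 0)
  keep <- gene_ids(cohort)[frac0 <= zero_fraction]
  if (length(keep) == 0) {
    warn("All genes removed by the zero-expression filter.")
    empty <- cohort$values[integer(0), , drop = FALSE]
    return(expression_cohort(
      empty, gene_class = character(),
      condition = setNames(cohort$samples$condition,
                           cohort$samples$sample_id),
      purity = setNames(cohort$samples$purity, cohort$samples$sample_id),
      survival = data.frame(sample = cohort$samples$sample_id,
                            time = cohort$samples$time,
                            event = cohort$samples$event)))
  }
  subset_cohort(cohort, genes = keep)
}
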