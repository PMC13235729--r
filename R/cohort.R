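#' Construct an expression cohort
#'
#' An `expression_cohort` bundles a genes-by-samples expression matrix on the
#' log2(TPM + 1) scale with per-gene class labels (`lncRNA`, `immune`, `SSG`,
#' `other`) and per-sample metadata: condition (`tumor`/`normal`), tumour
#' purity in \[0, 1\], and optional survival (`time`, `event`). It is the input
#' container for every stage of the triplet pipeline.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames and no missing entries.
#' @param gene_class Named character vector mapping gene ids to one of
#'   `r toString(GENE_CLASSES)`. Genes not named default to `"other"`.
#' @param condition Named character vector mapping sample ids to
#'   `"tumor"`/`"normal"`; unnamed entries default to `NA`.
#' @param purity Named numeric vector of tumour purities in \[0, 1\] (`NA`
#'   allowed, e.g. for normal samples).
#' @param survival Data frame with columns `sample`, `time`, `event` (event
#'   coded 0/1), or `NULL`.
#'
#' @return An object of class `expression_cohort`: a list with elements
#'   `values` (matrix), `genes` (tibble: `gene_id`, `class`) and `samples`
#'   (tibble: `sample_id`, `condition`, `purity`, `time`, `event`).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("L1", "S1", "G1"), paste0("s", 1:4)))
#' expression_cohort(m, gene_class = c(L1 = "lncRNA", S1 = "SSG", G1 = "immune"))
expression_cohort <- function(values, gene_class = NULL, condition = NULL,
                              purity = NULL, survival = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    abort("`values` must have gene rownames and sample colnames.")
  }
  if (nrow(values) == 0) rownames(values) <- character()
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("Duplicate gene ids: ", toString(head(dups, 5))))
  }
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Missing expression value for gene '%s', sample '%s'.",
                  rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }

  gene_ids <- rownames(values)
  cls <- rep("other", length(gene_ids))
  names(cls) <- gene_ids
  if (!is.null(gene_class)) {
    bad <- setdiff(unique(gene_class), GENE_CLASSES)
    if (length(bad) > 0) {
      abort(paste0("Unknown gene class(es): ", toString(bad)))
    }
    keep <- intersect(names(gene_class), gene_ids)
    cls[keep] <- gene_class[keep]
  }

  sample_ids <- colnames(values)
  cond <- rep(NA_character_, length(sample_ids))
  names(cond) <- sample_ids
  if (!is.null(condition)) {
    keep <- intersect(names(condition), sample_ids)
    cond[keep] <- as.character(condition[keep])
  }
  pur <- rep(NA_real_, length(sample_ids))
  names(pur) <- sample_ids
  if (!is.null(purity)) {
    keep <- intersect(names(purity), sample_ids)
    pur[keep] <- as.numeric(purity[keep])
    ok <- is.na(pur) | (pur >= 0 & pur <= 1)
    if (!all(ok)) {
      abort(paste0("Purity outside [0, 1] for sample(s): ",
                   toString(head(sample_ids[!ok], 5))))
    }
  }
  tim <- rep(NA_real_, length(sample_ids))
  evt <- rep(NA_integer_, length(sample_ids))
  names(tim) <- names(evt) <- sample_ids
  if (!is.null(survival)) {
    survival <- as.data.frame(survival)
    stopifnot(all(c("sample", "time", "event") %in% names(survival)))
    keep <- intersect(survival$sample, sample_ids)
    rows <- match(keep, survival$sample)
    tim[keep] <- as.numeric(survival$time[rows])
    evt[keep] <- as.integer(survival$event[rows])
    if (any(tim[keep] < 0, na.rm = TRUE)) abort("Survival times must be >= 0.")
    if (!all(evt[keep] %in% c(0L, 1L, NA_integer_))) {
      abort("Survival events must be coded 0/1.")
    }
  }

  structure(
    list(
      values = values,
      genes = tibble(gene_id = gene_ids, class = unname(cls)),
      samples = tibble(sample_id = sample_ids, condition = unname(cond),
                       purity = unname(pur), time = unname(tim),
                       event = unname(evt))
    ),
    class = "expression_cohort"
  )
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat(sprintf("<expression_cohort> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cls <- table(factor(x$genes$class, levels = GENE_CLASSES))
  cat("  gene classes:",
      paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cond <- table(x$samples$condition, useNA = "ifany")
  cat("  conditions:  ",
      paste(sprintf("%s=%d", names(cond), cond), collapse = ", "), "\n")
  cat(sprintf("  purity: %d/%d samples; survival: %d samples\n",
              sum(!is.na(x$samples$purity)), ncol(x$values),
              sum(!is.na(x$samples$time) & !is.na(x$samples$event))))
  invisible(x)
}

#' Cohort accessors
#'
#' @param cohort An [expression_cohort()].
#' @return `gene_ids()`/`sample_ids()` return character vectors;
#'   `gene_classes()` a named character vector; `expr_values()` the numeric
#'   matrix; `sample_info()` the sample metadata tibble.
#' @export
gene_ids <- function(cohort) cohort$genes$gene_id

#' @rdname gene_ids
#' @export
sample_ids <- function(cohort) cohort$samples$sample_id

#' @rdname gene_ids
#' @export
gene_classes <- function(cohort) {
  setNames(cohort$genes$class, cohort$genes$gene_id)
}

#' @rdname gene_ids
#' @export
expr_values <- function(cohort) cohort$values

#' @rdname gene_ids
#' @export
sample_info <- function(cohort) cohort$samples

#' Subset a cohort by genes and/or samples
#'
#' @param cohort An [expression_cohort()].
#' @param genes,samples Character vectors of ids to keep (`NULL` keeps all).
#' @return A new `expression_cohort`, order following the requested ids.
#' @export
subset_cohort <- function(cohort, genes = NULL, samples = NULL) {
  genes <- genes %||% gene_ids(cohort)
  samples <- samples %||% sample_ids(cohort)
  missing_g <- setdiff(genes, gene_ids(cohort))
  if (length(missing_g) > 0) {
    abort(paste0("Genes not in cohort: ", toString(head(missing_g, 5))))
  }
  missing_s <- setdiff(samples, sample_ids(cohort))
  if (length(missing_s) > 0) {
    abort(paste0("Samples not in cohort: ", toString(head(missing_s, 5))))
  }
  smp <- cohort$samples[match(samples, cohort$samples$sample_id), ]
  surv <- data.frame(sample = smp$sample_id, time = smp$time,
                     event = smp$event)
  expression_cohort(
    cohort$values[genes, samples, drop = FALSE],
    gene_class = gene_classes(cohort)[genes],
    condition = setNames(smp$condition, smp$sample_id),
    purity = setNames(smp$purity, smp$sample_id),
    survival = surv
  )
}

#' Extract tumour samples with usable purity
#'
#' Convenience used by the purity-adjusted stages: keeps samples labelled
#' `"tumor"` (or all samples when no condition labels are present) that carry
#' a non-missing purity value.
#'
#' @param cohort An [expression_cohort()].
#' @return An `expression_cohort` restricted to those samples.
#' @export
tumor_purity_samples <- function(cohort) {
  smp <- cohort$samples
  keep <- (is.na(smp$condition) | smp$condition == "tumor") & !is.na(smp$purity)
  if (!any(keep)) abort("No tumor samples with purity available.")
  subset_cohort(cohort, samples = smp$sample_id[keep])
}
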