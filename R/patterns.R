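# Gaussian log-likelihood of x at its MLEs (mean, variance); 2 parameters.
ll_marginal <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  if (s2 < 1e-15 * max(1, mean(x^2))) {
    abort("Degenerate likelihood: (near-)constant variable.")
  }
  list(loglik = -n / 2 * (log(2 * pi) + log(s2) + 1), k = 2L)
}

# Gaussian log-likelihood of y | parents via OLS at the MLE variance;
# 2 + ncol(parents) parameters (intercept, slopes, variance).
ll_conditional <- function(y, parents) {
  n <- length(y)
  X <- cbind(1, parents)
  fit <- stats::.lm.fit(X, y)
  s2 <- mean(fit$residuals^2)
  if (s2 < 1e-15 * max(1, mean(y^2))) {
    abort("Degenerate likelihood: zero residual variance.")
  }
  list(loglik = -n / 2 * (log(2 * pi) + log(s2) + 1),
       k = 1L + ncol(X))
}

#' Fit one regulatory pattern by maximum likelihood
#'
#' Factorises the joint density of the triplet (`L` lncRNA, `S` SSG, `I`
#' immune gene) according to the pattern's DAG and fits each factor as a
#' linear-Gaussian conditional by maximum likelihood:
#'
#' * `IR`:  `P(L) P(S|L) P(I|L)`
#' * `CR`:  `P(L) P(I) P(S|L,I)`
#' * `LIS`: `P(L) P(I|L) P(S|I)`
#' * `LSI`: `P(L) P(S|L) P(I|S)`
#'
#' A marginal factor has 2 parameters, a one-parent conditional 3, a
#' two-parent conditional 4; every pattern totals `k = 8`.
#'
#' @param L,S,I Numeric vectors of equal length `n >= 8`, non-constant.
#' @param pattern One of `"IR"`, `"CR"`, `"LIS"`, `"LSI"`.
#' @return List with `loglik` (sum over factors) and `k` (total parameter
#'   count).
#' @export
fit_pattern <- function(L, S, I, pattern) {
  n <- length(L)
  if (length(S) != n || length(I) != n) abort("Vectors must have equal length.")
  if (n < 8) abort("Need at least 8 observations.")
  if (!pattern %in% PATTERNS) {
    abort(paste0("Unknown pattern '", pattern, "'."))
  }
  factors <- switch(pattern,
    IR  = list(ll_marginal(L), ll_conditional(S, cbind(L)),
               ll_conditional(I, cbind(L))),
    CR  = list(ll_marginal(L), ll_marginal(I),
               ll_conditional(S, cbind(L, I))),
    LIS = list(ll_marginal(L), ll_conditional(I, cbind(L)),
               ll_conditional(S, cbind(I))),
    LSI = list(ll_marginal(L), ll_conditional(S, cbind(L)),
               ll_conditional(I, cbind(S)))
  )
  list(loglik = sum(vapply(factors, `[[`, numeric(1), "loglik")),
       k = sum(vapply(factors, `[[`, integer(1), "k")))
}

#' Bayesian information criterion
#'
#' `BIC = k ln(n) - 2 ln(L)` (lower is better).
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of parameters.
#' @param n Sample size (>= 2 when `k > 0`).
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) {
  if (any(k > 0) && any(n < 2)) abort("`n` must be >= 2.")
  k * log(n) - 2 * loglik
}

#' BIC weights of competing models
#'
#' Converts BIC values into model weights
#' `omega_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = BIC_i - min(BIC)`. Weights sum to 1, are invariant to adding
#' a constant to all BICs, and are all equal when the BICs tie.
#'
#' @param bics Numeric vector of BIC values.
#' @return Numeric weights of the same length.
#' @export
bic_weights <- function(bics) {
  delta <- bics - min(bics)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Select the best-supported regulatory pattern for a triplet
#'
#' Fits all four candidate patterns ([fit_pattern()]), ranks them by BIC and
#' converts BIC differences `Delta_i = BIC_i - BIC_min` into BIC weights
#' `omega_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)`. The selected
#' pattern minimises the BIC (equivalently maximises the weight); exact ties
#' are broken in the documented order IR < CR < LIS < LSI.
#'
#' @inheritParams fit_pattern
#' @return Object of class `pattern_fit`: list with `table` (tibble:
#'   `pattern`, `loglik`, `k`, `bic`, `delta`, `weight`), `selected` and
#'   `n`. Weights sum to 1 and `min(delta) = 0`.
#' @export
select_pattern <- function(L, S, I) {
  fits <- lapply(PATTERNS, function(p) fit_pattern(L, S, I, p))
  tab <- tibble(
    pattern = PATTERNS,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, integer(1), "k"))
  tab$bic <- bic(tab$loglik, tab$k, length(L))
  tab$delta <- tab$bic - min(tab$bic)
  tab$weight <- bic_weights(tab$bic)
  structure(list(table = tab, selected = PATTERNS[which.min(tab$bic)],
                 n = length(L)),
            class = "pattern_fit")
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat(sprintf("<pattern_fit> n = %d, selected = %s\n", x$n, x$selected))
  print(x$table)
  invisible(x)
}

#' Infer regulatory patterns for a table of triplets
#'
#' Runs [select_pattern()] on every (lncRNA, immune gene, SSG) triplet of an
#' assembled triplet table, expanding pairs with several immune partners
#' into one row per partner, and summarises per-pattern BIC weights.
#'
#' @param cohort An [expression_cohort()]; tumour samples are used.
#' @param triplets Tibble with columns `lncRNA`, `ssg` and either `immune`
#'   (one gene per row) or `immune_genes` (list-column, e.g. from
#'   [assemble_triplets()]).
#' @return Tibble with one row per triplet: `lncRNA`, `immune`, `ssg`,
#'   `selected`, one `weight_*` column per pattern, and `fit` (list-column
#'   of `pattern_fit` objects).
#' @export
infer_patterns <- function(cohort, triplets) {
  if (!"immune" %in% names(triplets) && "immune_genes" %in% names(triplets)) {
    triplets <- triplets |>
      select("lncRNA", "ssg", "immune_genes") |>
      tidyr::unnest(cols = "immune_genes") |>
      rename(immune = "immune_genes")
  }
  stopifnot(all(c("lncRNA", "immune", "ssg") %in% names(triplets)))
  cond <- cohort$samples$condition
  use <- if (any(!is.na(cond) & cond == "tumor")) {
    which(!is.na(cond) & cond == "tumor")
  } else {
    seq_along(cond)
  }
  vals <- cohort$values[, use, drop = FALSE]
  rows <- pmap(list(triplets$lncRNA, triplets$immune, triplets$ssg),
               function(ln, im, sg) {
    fit <- select_pattern(vals[ln, ], vals[sg, ], vals[im, ])
    w <- setNames(fit$table$weight, paste0("weight_", fit$table$pattern))
    c(list(lncRNA = ln, immune = im, ssg = sg, selected = fit$selected),
      as.list(w), list(fit = list(fit)))
  })
  bind_rows(lapply(rows, as_tibble))
}

#' Summarise pattern proportions across triplets
#'
#' @param pattern_table Output of [infer_patterns()].
#' @return Tibble `pattern`, `n`, `proportion` over the four patterns.
#' @export
pattern_proportions <- function(pattern_table) {
  tab <- table(factor(pattern_table$selected, levels = PATTERNS))
  tibble(pattern = PATTERNS, n = as.integer(tab),
         proportion = as.integer(tab) / max(sum(tab), 1))
}
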