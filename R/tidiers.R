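#' Tidy a pattern fit
#'
#' @param x A `pattern_fit` from [select_pattern()].
#' @param ... Unused.
#' @return Tibble with one row per candidate pattern: `pattern`, `loglik`,
#'   `k`, `bic`, `delta`, `weight`, `selected` (logical).
#' @export
tidy.pattern_fit <- function(x, ...) {
  x$table |> mutate(selected = .data$pattern == x$selected)
}

#' @rdname tidy.pattern_fit
#' @return `glance()` returns a one-row tibble: `selected`, `weight`,
#'   `delta_next` (BIC gap to the runner-up), `n`.
#' @export
glance.pattern_fit <- function(x, ...) {
  tab <- x$table |> arrange(.data$bic)
  tibble(selected = x$selected, weight = tab$weight[1],
         delta_next = tab$bic[2] - tab$bic[1], n = x$n)
}

#' Tidy a triplet score model
#'
#' @param x A `triplet_score_model` from [fit_triplet_score()].
#' @param ... Unused.
#' @return Tibble of Cox coefficients: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`.
#' @export
tidy.triplet_score_model <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = c("lncRNA", "immune", "ssg"),
         estimate = unname(s[, "coef"]),
         std_error = unname(s[, "se(coef)"]),
         statistic = unname(s[, "z"]),
         p_value = unname(s[, "Pr(>|z|)"]))
}

#' @rdname tidy.triplet_score_model
#' @return `glance()` returns a one-row tibble: `n`, `n_events`,
#'   `concordance`, `logtest_p`.
#' @export
glance.triplet_score_model <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n = s$n, n_events = s$nevent,
         concordance = unname(s$concordance["C"]),
         logtest_p = unname(s$logtest["pvalue"]))
}

#' Tidy a WPC permutation test
#'
#' @param x A `wpc_permutation` from [permutation_test()].
#' @param ... Unused.
#' @return One-row tibble: `observed`, `perm_p`, `n_perm`, `null_mean`,
#'   `null_sd`.
#' @export
tidy.wpc_permutation <- function(x, ...) {
  tibble(observed = x$observed, perm_p = x$perm_p, n_perm = x$n_perm,
         null_mean = mean(x$null_scores), null_sd = sd(x$null_scores))
}
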