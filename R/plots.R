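#' Plot BIC weights of the four candidate patterns
#'
#' @param object A `pattern_fit` from [select_pattern()].
#' @param ... Unused.
#' @return A ggplot barchart of the BIC weights, selected pattern
#'   highlighted.
#' @export
autoplot.pattern_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pattern,
                                              levels = PATTERNS),
                                   y = .data$weight,
                                   fill = .data$selected)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "regulatory pattern", y = "BIC weight ω",
                  title = sprintf("Selected pattern: %s (n = %d)",
                                  object$selected, object$n)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the top propagated scores
#'
#' @param object A `propagation_result` from [rwr()].
#' @param top_n How many nodes to show.
#' @param ... Unused.
#' @return A ggplot lollipop chart of the highest propagation scores.
#' @export
autoplot.propagation_result <- function(object, top_n = 20, ...) {
  df <- head(as_tibble(object), top_n)
  df$node <- factor(df$node, levels = rev(df$node))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$node)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$node),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = "propagation score", y = NULL,
                  title = sprintf("Top %d nodes (restart = %.2f)",
                                  nrow(df), attr(object, "restart"))) +
    ggplot2::theme_minimal()
}

#' Plot the permutation null of a WPC score
#'
#' @param x A `wpc_permutation` from [permutation_test()].
#' @return A ggplot histogram of the null WPC scores with the observed
#'   score marked.
#' @export
plot_wpc_null <- function(x) {
  stopifnot(inherits(x, "wpc_permutation"))
  df <- tibble(null = x$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey75", colour = "white") +
    ggplot2::geom_vline(xintercept = x$observed, colour = "#b2182b",
                        linewidth = 0.8) +
    ggplot2::labs(x = "null WPC score", y = "permutations",
                  title = sprintf("Observed WPC = %.3g (p = %g)",
                                  x$observed, x$perm_p)) +
    ggplot2::theme_minimal()
}

#' Boxplot of pair versus triplet bootstrap stability
#'
#' @param stability Tibble from [stability_analysis()] (columns `s_pair`,
#'   `s_triplet`).
#' @return A ggplot comparing the two stability distributions.
#' @export
plot_stability_summary <- function(stability) {
  df <- stability |>
    select("s_pair", "s_triplet") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "level",
                        values_to = "stability") |>
    mutate(level = ifelse(.data$level == "s_pair", "pair (MI)",
                          "triplet (CMI)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$stability)) +
    ggplot2::geom_boxplot(fill = "grey85", width = 0.5,
                          outlier.size = 0.7) +
    ggplot2::labs(x = NULL, y = "bootstrap stability",
                  title = "lncRNA-SSG pair vs triplet stability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a cutoff stratification
#'
#' @param strat A `cutoff_stratification` from [optimal_cutoff_stratify()].
#' @param time,event The survival data the stratification was computed on.
#' @return A ggplot of the two Kaplan-Meier step curves.
#' @export
plot_km_strata <- function(strat, time, event) {
  stopifnot(inherits(strat, "cutoff_stratification"))
  sf <- survival::survfit(survival::Surv(time, event) ~ strat$group)
  groups <- sub("^.*=", "", rep(names(sf$strata), sf$strata))
  df <- tibble(time = sf$time, surv = sf$surv, group = groups)
  df <- bind_rows(tibble(time = 0, surv = 1,
                         group = unique(groups)), df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::scale_colour_manual(values = c(low = "#2166ac",
                                            high = "#b2182b")) +
    ggplot2::labs(x = "time", y = "survival probability",
                  colour = "score group",
                  title = sprintf("Log-rank p = %.3g (cutoff %.3g)",
                                  strat$logrank_p, strat$cutoff)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
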