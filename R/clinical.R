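#' Fit a prognostic triplet score
#'
#' Fits a three-covariate Cox proportional-hazards model on the expression
#' of the triplet's lncRNA, immune gene and SSG, and scores every sample by
#' the linear predictor
#' `score = coef_lnc * exp_lnc + coef_imm * exp_imm + coef_ssg * exp_ssg`.
#' The Cox numerics are delegated to [survival::coxph()]; the contribution
#' here is the score construction contract.
#'
#' @param cohort An [expression_cohort()] with survival metadata (at least
#'   20 events among usable samples).
#' @param triplet Character vector or list with elements/ids
#'   `lncRNA`, `immune`, `ssg` (unnamed vectors are taken in that order).
#' @return Object of class `triplet_score_model`: list with `triplet`,
#'   `coef` (named length-3 vector), `scores` (tibble `sample_id`, `score`
#'   over all samples), and `fit` (the `coxph` object).
#' @export
fit_triplet_score <- function(cohort, triplet) {
  trip <- unlist(triplet)
  if (is.null(names(trip)) || !all(c("lncRNA", "immune", "ssg") %in% names(trip))) {
    stopifnot(length(trip) == 3)
    names(trip) <- c("lncRNA", "immune", "ssg")
  }
  smp <- cohort$samples
  usable <- !is.na(smp$time) & !is.na(smp$event)
  if (sum(smp$event[usable], na.rm = TRUE) < 20) {
    abort("Need at least 20 events to fit the triplet score.")
  }
  dat <- data.frame(
    time = smp$time[usable], event = smp$event[usable],
    lnc = cohort$values[trip[["lncRNA"]], usable],
    imm = cohort$values[trip[["immune"]], usable],
    ssg = cohort$values[trip[["ssg"]], usable])
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ lnc + imm + ssg,
                    data = dat),
    warning = function(w) {
      if (grepl("converge|infinite", conditionMessage(w))) {
        abort(paste0("Cox fit did not converge: ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    })
  cf <- setNames(coef(fit), c("coef_lnc", "coef_imm", "coef_ssg"))
  expr3 <- t(cohort$values[trip, , drop = FALSE])
  scores <- as.numeric(expr3 %*% unname(cf))
  structure(list(triplet = trip, coef = cf,
                 scores = tibble(sample_id = sample_ids(cohort),
                                 score = scores),
                 fit = fit),
            class = "triplet_score_model")
}

#' @export
print.triplet_score_model <- function(x, ...) {
  cat(sprintf("<triplet_score_model> %s / %s / %s\n",
              x$triplet[["lncRNA"]], x$triplet[["immune"]],
              x$triplet[["ssg"]]))
  print(round(x$coef, 4))
  invisible(x)
}

# log-rank chi-square for a binary split, via survival::survdiff
logrank_stat <- function(time, event, group) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd$chisq, p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Maximally selected log-rank stratification
#'
#' Evaluates the two-group log-rank statistic at every candidate cutoff on
#' the score (samples with `score <= cutoff` form the low group) for which
#' both groups contain at least `min_group_fraction` of the samples, and
#' returns the cutoff maximising the statistic together with the
#' corresponding naive log-rank p-value. With `min_group_fraction = 0.5`
#' and even `n`, only the median split is admissible. Ties on the statistic
#' keep the smallest cutoff. Note the selected p-value inherits the
#' multiple-testing optimism of the maximally selected statistic; it is
#' reported as-is.
#'
#' @param scores Numeric per-sample scores (not all identical).
#' @param time,event Survival time and 0/1 event indicator, same length.
#' @param min_group_fraction Minimum fraction of samples per group.
#' @return List of class `cutoff_stratification`: `cutoff`, `group`
#'   (factor `"low"`/`"high"`), `statistic` (log-rank chi-square),
#'   `logrank_p`, and `candidates` (tibble of all admissible cutoffs with
#'   their statistics).
#' @export
optimal_cutoff_stratify <- function(scores, time, event,
                                    min_group_fraction = 0.1) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (max(scores) == min(scores)) abort("All scores are identical.")
  uniq <- sort(unique(scores))
  cand <- uniq[-length(uniq)]
  n_low <- vapply(cand, function(cc) sum(scores <= cc), numeric(1))
  ok <- n_low / n >= min_group_fraction - 1e-12 &
    (n - n_low) / n >= min_group_fraction - 1e-12
  cand <- cand[ok]
  if (length(cand) == 0) {
    abort("No cutoff satisfies `min_group_fraction` for both groups.")
  }
  stats <- vapply(cand, function(cc) {
    logrank_stat(time, event, factor(scores > cc,
                                     levels = c(FALSE, TRUE)))$chisq
  }, numeric(1))
  best <- which.max(stats)  # first maximum -> smallest cutoff on ties
  cutoff <- cand[best]
  group <- factor(ifelse(scores > cutoff, "high", "low"),
                  levels = c("low", "high"))
  structure(list(cutoff = cutoff, group = group, statistic = stats[best],
                 logrank_p = pchisq(stats[best], 1, lower.tail = FALSE),
                 candidates = tibble(cutoff = cand, statistic = stats)),
            class = "cutoff_stratification")
}

#' @export
print.cutoff_stratification <- function(x, ...) {
  cat(sprintf(
    "<cutoff_stratification> cutoff = %.4g (low n=%d, high n=%d), chisq = %.3f, log-rank p = %.3g\n",
    x$cutoff, sum(x$group == "low"), sum(x$group == "high"),
    x$statistic, x$logrank_p))
  invisible(x)
}

#' Classify lncRNA breadth across cancer types
#'
#' Labels each lncRNA by the number of cancer types in which it appears:
#' `common` when detected in more than 10 cancer types, `specific` when in
#' no more than 2, `intermediate` otherwise. When `ssg` and `pattern`
#' columns are present, lncRNA-SSG pairs occurring in more than 10 cancer
#' types with at least 2 distinct selected patterns are flagged as
#' pattern-variable pairs.
#'
#' @param records Tibble with columns `lncRNA`, `cancer_type`, and
#'   optionally `ssg`, `pattern`.
#' @return List of class `breadth_class`: `lncRNA_class` (tibble `lncRNA`,
#'   `n_cancer_types`, `label`) and `pattern_variable_pairs` (tibble
#'   `lncRNA`, `ssg`, `n_cancer_types`, `n_patterns`).
#' @export
classify_breadth <- function(records) {
  stopifnot(all(c("lncRNA", "cancer_type") %in% names(records)))
  lnc <- records |>
    group_by(.data$lncRNA) |>
    summarise(n_cancer_types = dplyr::n_distinct(.data$cancer_type),
              .groups = "drop") |>
    mutate(label = dplyr::case_when(
      .data$n_cancer_types > 10 ~ "common",
      .data$n_cancer_types <= 2 ~ "specific",
      TRUE ~ "intermediate"))
  pv <- tibble(lncRNA = character(), ssg = character(),
               n_cancer_types = integer(), n_patterns = integer())
  if (all(c("ssg", "pattern") %in% names(records))) {
    pv <- records |>
      group_by(.data$lncRNA, .data$ssg) |>
      summarise(n_cancer_types = dplyr::n_distinct(.data$cancer_type),
                n_patterns = dplyr::n_distinct(.data$pattern),
                .groups = "drop") |>
      filter(.data$n_cancer_types > 10, .data$n_patterns >= 2)
  }
  structure(list(lncRNA_class = lnc, pattern_variable_pairs = pv),
            class = "breadth_class")
}

#' Hypergeometric set-overlap significance
#'
#' Upper-tail probability `P(overlap >= observed)` that two gene sets drawn
#' from a universe of `universe_size` genes share at least the observed
#' number of members, via [stats::phyper()].
#'
#' @param set_a,set_b Character vectors (deduplicated internally).
#' @param universe_size Size of the gene universe (>= both set sizes).
#' @return The hypergeometric upper-tail p-value.
#' @export
overlap_significance <- function(set_a, set_b, universe_size) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (length(a) > universe_size || length(b) > universe_size) {
    abort("Set sizes cannot exceed `universe_size`.")
  }
  ov <- length(intersect(a, b))
  phyper(ov - 1, length(a), universe_size - length(a), length(b),
         lower.tail = FALSE)
}

#' Prognostic screen of triplets
#'
#' For each triplet, summarises the three genes by their per-sample mean
#' expression, then tests the association of that summary with overall
#' survival twice: a univariate Cox regression (Wald p) and a log-rank test
#' at the median split. A triplet is flagged prognostic when both p-values
#' fall below `alpha` — the dual criterion guards against either test's
#' idiosyncrasies. The equal-weight summary (rather than a Cox-fitted
#' score) keeps the screen free of outcome-driven selection bias.
#'
#' @param cohort An [expression_cohort()] with survival metadata.
#' @param triplets Tibble with columns `lncRNA`, `immune`, `ssg` (list
#'   columns from [assemble_triplets()] are expanded).
#' @param alpha Significance threshold for both tests.
#' @return Tibble: triplet ids, `cox_p`, `logrank_p`, `prognostic`.
#' @export
prognostic_screen <- function(cohort, triplets, alpha = 0.05) {
  if (!"immune" %in% names(triplets) && "immune_genes" %in% names(triplets)) {
    triplets <- triplets |>
      select("lncRNA", "ssg", "immune_genes") |>
      tidyr::unnest(cols = "immune_genes") |>
      rename(immune = "immune_genes")
  }
  smp <- cohort$samples
  usable <- which(!is.na(smp$time) & !is.na(smp$event))
  if (length(usable) < 10) abort("Survival metadata required (>= 10 samples).")
  time <- smp$time[usable]
  event <- smp$event[usable]
  rows <- pmap(list(triplets$lncRNA, triplets$immune, triplets$ssg),
               function(ln, im, sg) {
    score <- colMeans(cohort$values[c(ln, im, sg), usable, drop = FALSE])
    cox_p <- tryCatch({
      fit <- survival::coxph(survival::Surv(time, event) ~ score)
      summary(fit)$coefficients[1, "Pr(>|z|)"]
    }, error = function(e) NA_real_)
    lr_p <- tryCatch({
      grp <- factor(score > median(score), levels = c(FALSE, TRUE))
      if (length(unique(grp)) < 2) NA_real_ else
        logrank_stat(time, event, grp)$p
    }, error = function(e) NA_real_)
    tibble(lncRNA = ln, immune = im, ssg = sg, cox_p = cox_p,
           logrank_p = lr_p,
           prognostic = !is.na(cox_p) & !is.na(lr_p) &
             cox_p < alpha & lr_p < alpha)
  })
  bind_rows(rows)
}
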