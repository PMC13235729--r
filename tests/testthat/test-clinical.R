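make_survival_cohort <- function(n = 400, effect = 1, seed = 17) {
  specs <- list(triplet_spec("CR", a = 0.8, b = 0.8, noise_sd = 1))
  cfg <- synthetic_cohort_config(n, specs, n_null_genes = 9, seed = seed,
                                 survival_baseline = 0.2,
                                 survival_effect = effect,
                                 censor_horizon = 25)
  generate_cohort(cfg)
}

test_that("triplet scores are the stated linear combination", {
  res <- make_survival_cohort()
  trip <- c(lncRNA = res$provenance$lncRNA, immune = res$provenance$immune,
            ssg = res$provenance$ssg)
  model <- fit_triplet_score(res$cohort, trip)
  v <- expr_values(res$cohort)
  manual <- model$coef[["coef_lnc"]] * v[trip[["lncRNA"]], ] +
    model$coef[["coef_imm"]] * v[trip[["immune"]], ] +
    model$coef[["coef_ssg"]] * v[trip[["ssg"]], ]
  expect_equal(model$scores$score, unname(manual), tolerance = 1e-12)
  # affine equivariance in each coordinate: doubling a gene's expression
  # doubles its contribution
  expect_equal(model$coef[["coef_lnc"]] * 2 * v[trip[["lncRNA"]], 1],
               2 * (model$coef[["coef_lnc"]] * v[trip[["lncRNA"]], 1]))
})

test_that("fitted scores recover a planted survival gradient", {
  res <- make_survival_cohort(effect = 1)
  trip <- c(lncRNA = res$provenance$lncRNA, immune = res$provenance$immune,
            ssg = res$provenance$ssg)
  model <- fit_triplet_score(res$cohort, trip)
  planted <- colMeans(expr_values(res$cohort)[unlist(trip), ])
  expect_gt(cor(model$scores$score, planted), 0.7)
  # too few events is an error
  tiny <- make_survival_cohort(n = 30, seed = 18)
  expect_error(fit_triplet_score(
    subset_cohort(tiny$cohort,
                  samples = sample_ids(tiny$cohort)[1:12]),
    trip), "20 events")
})

test_that("maximally selected cutoff matches the exhaustive-split oracle", {
  withr::with_seed(19, {
    n <- 60
    scores <- rnorm(n)
    time <- rexp(n, 0.2 * exp(0.8 * scores))
    event <- rbinom(n, 1, 0.8)
  })
  strat <- optimal_cutoff_stratify(scores, time, event,
                                   min_group_fraction = 0.1)
  # independent oracle: first-principles log-rank over every split
  uniq <- sort(unique(scores))
  best <- -Inf; best_cut <- NA
  for (cc in uniq[-length(uniq)]) {
    high <- scores > cc
    if (min(mean(high), 1 - mean(high)) < 0.1) next
    chi <- logrank_chisq_oracle(time, event, high)
    if (chi > best + 1e-12) { best <- chi; best_cut <- cc }
  }
  expect_equal(strat$cutoff, best_cut)
  expect_equal(strat$statistic, best, tolerance = 1e-8)
  expect_equal(strat$logrank_p, pchisq(best, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("cutoff search respects group-size constraints and separation", {
  # two well-separated clusters with very different hazards
  withr::with_seed(20, {
    scores <- c(rnorm(100, 0, 0.3), rnorm(100, 5, 0.3))
    time <- c(rexp(100, 0.2), rexp(100, 1))
    event <- rep(1L, 200)
  })
  strat <- optimal_cutoff_stratify(scores, time, event)
  # the selected split separates the clusters (cutoff is a score value, so
  # it sits at the upper fringe of the low cluster)
  expect_true(all(scores[strat$group == "high"] > 2.5 |
                    scores[strat$group == "high"] >
                      quantile(scores[scores < 2.5], 0.9)))
  expect_gte(mean(scores[strat$group == "high"] > 2.5), 0.95)
  expect_true(all(scores[scores > 2.5] %in% scores[strat$group == "high"]))
  expect_lt(strat$logrank_p, 1e-6)
  # min_group_fraction = 0.5 with even n forces the median split
  s <- c(1, 2, 3, 4, 5, 6)
  strat2 <- optimal_cutoff_stratify(s, c(3, 1, 4, 2, 6, 5),
                                    c(1, 1, 0, 1, 1, 1),
                                    min_group_fraction = 0.5)
  expect_equal(strat2$cutoff, 3)
  expect_equal(as.character(strat2$group),
               c("low", "low", "low", "high", "high", "high"))
  expect_error(optimal_cutoff_stratify(rep(1, 10), rexp(10), rep(1, 10)),
               "identical")
})

test_that("breadth classification applies the >10 / <=2 rules", {
  records <- tibble::tibble(
    lncRNA = c(rep("wide", 11), rep("narrow", 2), rep("mid", 5)),
    cancer_type = c(paste0("C", 1:11), c("C1", "C2"), paste0("C", 1:5)),
    ssg = "S1",
    pattern = c(rep(c("CR", "LIS"), length.out = 11), "CR", "CR",
                rep("CR", 5)))
  bc <- classify_breadth(records)
  lab <- setNames(bc$lncRNA_class$label, bc$lncRNA_class$lncRNA)
  expect_equal(unname(lab[c("wide", "narrow", "mid")]),
               c("common", "specific", "intermediate"))
  # pattern-variable pair: wide/S1 spans 11 cancers with 2 patterns
  expect_equal(nrow(bc$pattern_variable_pairs), 1L)
  expect_equal(bc$pattern_variable_pairs$lncRNA, "wide")
})

test_that("hypergeometric overlap matches exact enumeration", {
  # universe 10, |a| = |b| = 5, full overlap: p = 1 / C(10, 5)
  expect_equal(overlap_significance(letters[1:5], letters[1:5], 10),
               1 / choose(10, 5))
  # overlap 0 is always achievable: p = 1
  expect_equal(overlap_significance(letters[1:3], letters[4:6], 12), 1)
  # brute-force combinatorial oracle on a small universe
  universe <- letters[1:12]
  set_a <- letters[1:5]
  k_b <- 4
  obs_overlap <- 2
  draws <- combn(12, k_b)
  exceed <- mean(apply(draws, 2, function(idx)
    length(intersect(universe[idx], set_a)) >= obs_overlap))
  expect_equal(
    phyper(obs_overlap - 1, 5, 7, k_b, lower.tail = FALSE), exceed)
  p_mine <- overlap_significance(set_a, c("a", "b", "f", "g"), 12)
  expect_equal(p_mine, exceed)
  # symmetry and monotonicity in the observed overlap
  expect_equal(overlap_significance(set_a, letters[3:7], 12),
               overlap_significance(letters[3:7], set_a, 12))
  p1 <- overlap_significance(letters[1:4], letters[1:4], 12)
  p2 <- overlap_significance(letters[1:4], letters[2:5], 12)
  expect_lt(p1, p2)
  expect_error(overlap_significance(letters[1:5], letters[1:3], 4),
               "universe")
})

test_that("prognostic screen flags planted effects and spares nulls", {
  # planted effect: flagged
  res <- make_survival_cohort(effect = 1)
  flagged <- vapply(1:5, function(s) {
    r <- make_survival_cohort(effect = 1, seed = 300 + s)
    prognostic_screen(r$cohort, r$provenance)$prognostic
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
  # null effect over many triplets: joint criterion keeps ~alpha or fewer
  null_res <- make_survival_cohort(effect = 0, seed = 23)
  cls <- gene_classes(null_res$cohort)
  nulls <- tidyr::expand_grid(
    lncRNA = names(cls)[cls == "lncRNA"][1:4],
    immune = names(cls)[cls == "immune"][1:3],
    ssg = names(cls)[cls == "SSG"][1:3])
  scr <- prognostic_screen(null_res$cohort, nulls)
  expect_lte(mean(scr$prognostic), 0.10)
})
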