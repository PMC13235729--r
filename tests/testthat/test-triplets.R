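test_that("partial correlation matches the residual-regression oracle", {
  devs <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      n <- 50
      cv <- rnorm(n)
      x <- 0.5 * cv + rnorm(n)
      y <- -0.3 * cv + rnorm(n)
      pc <- partial_correlation(x, y, cv)
      oracle <- cor(resid(lm(x ~ cv)), resid(lm(y ~ cv)))
      abs(pc$pcc - oracle)
    })
  }, numeric(1))
  expect_lt(max(devs), 1e-10)
})

test_that("partial correlation reduces correctly in edge cases", {
  withr::with_seed(1, {
    x <- rnorm(30)
    cv <- rnorm(30)
  })
  # x = y: pcc = 1
  expect_equal(partial_correlation(x, x, cv)$pcc, 1, tolerance = 1e-12)
  # orthogonalised inputs: pcc equals the raw Pearson correlation
  y <- withr::with_seed(2, rnorm(30))
  xo <- resid(lm(x ~ cv))
  yo <- resid(lm(y ~ cv))
  pc <- partial_correlation(xo, yo, cv)
  expect_equal(pc$pcc, pc$r_xy, tolerance = 1e-9)
  expect_error(partial_correlation(cv, y, cv), "Degenerate")
  expect_error(partial_correlation(x, y, rep(1, 30)), "constant")
  expect_error(partial_correlation(x[1:3], y[1:3], cv[1:3]), "at least 4")
})

test_that("WPC score follows the signed -log10 sum", {
  expect_equal(wpc_score(data.frame(beta = numeric(), p1 = numeric(),
                                    cor1 = numeric(), p2 = numeric(),
                                    cor2 = numeric())), 0)
  one <- data.frame(beta = 1, p1 = 0.1, cor1 = 0.5, p2 = 0.1, cor2 = 0.7)
  expect_equal(wpc_score(one), 2)
  cancel <- data.frame(beta = 1, p1 = 0.01, cor1 = 0.5, p2 = 0.01,
                       cor2 = -0.5)
  expect_equal(wpc_score(cancel), 0)
  # additive over genes; odd under a global sign flip
  two <- data.frame(beta = c(1, 2), p1 = c(0.1, 0.05), cor1 = c(1, -1),
                    p2 = c(0.2, 0.01), cor2 = c(1, 1))
  expect_equal(wpc_score(two),
               wpc_score(two[1, ]) + wpc_score(two[2, ]))
  flipped <- two
  flipped$cor1 <- -flipped$cor1
  flipped$cor2 <- -flipped$cor2
  expect_equal(wpc_score(flipped), -wpc_score(two))
  # underflow floored with warning
  zero <- data.frame(beta = 1, p1 = 0, cor1 = 1, p2 = 0.1, cor2 = 1)
  expect_warning(v <- wpc_score(zero, p_floor = 1e-4), "Flooring")
  expect_equal(v, 5)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- p[ord] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(ord)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  for (s in 1:20) {
    p <- withr::with_seed(s, runif(25)^2)
    expect_equal(bh_adjust(p), bh_oracle(p))
    expect_true(all(bh_adjust(p) >= p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("permutation p follows the N/n_perm exceedance formula", {
  cfg <- synthetic_cohort_config(150, list(triplet_spec("LSI", a = 1, b = 1,
                                                        noise_sd = 0.5)),
                                 n_null_genes = 12, seed = 61)
  res <- generate_cohort(cfg)
  cls <- gene_classes(res$cohort)
  imm <- names(cls)[cls == "immune"]
  beta <- setNames(rep(1, length(imm)), imm)
  pt <- permutation_test(res$cohort, res$provenance$lncRNA,
                         res$provenance$ssg, beta, n_perm = 200, seed = 3)
  expect_equal(pt$perm_p,
               sum(abs(pt$null_scores) >= abs(pt$observed)) / 200)
  expect_length(pt$null_scores, 200)
  expect_true(pt$perm_p %in% ((0:200) / 200))
  # the planted pair is far outside its own null
  expect_lt(pt$perm_p, 0.05)
  # determinism
  pt2 <- permutation_test(res$cohort, res$provenance$lncRNA,
                          res$provenance$ssg, beta, n_perm = 200, seed = 3)
  expect_identical(pt$null_scores, pt2$null_scores)
})

test_that("vectorised null WPC agrees with direct recomputation", {
  cohort <- generate_null_cohort(10, 80, seed = 71)
  imm <- names(gene_classes(cohort))[gene_classes(cohort) == "immune"]
  lnc <- names(gene_classes(cohort))[gene_classes(cohort) == "lncRNA"][1]
  ssg <- names(gene_classes(cohort))[gene_classes(cohort) == "SSG"][1]
  beta <- setNames(runif(length(imm), 0.5, 1), imm)
  pt <- permutation_test(cohort, lnc, ssg, beta, n_perm = 100, seed = 5)
  # recompute a few null scores by brute force with the same permutations
  tp <- tumor_purity_samples(cohort)
  L <- expr_values(tp)[lnc, ]
  S <- expr_values(tp)[ssg, ]
  G <- t(expr_values(tp)[imm, , drop = FALSE])
  purity <- sample_info(tp)$purity
  n <- length(L)
  perms <- withr::with_seed(5, lapply(1:100, function(b) sample.int(n)))
  for (b in c(1, 50, 100)) {
    Lp <- L[perms[[b]]]
    terms <- tibble::tibble(
      beta = unname(beta[imm]),
      p1 = vapply(imm, function(g)
        partial_correlation(Lp, expr_values(tp)[g, ], purity)$p,
        numeric(1)),
      cor1 = vapply(imm, function(g)
        partial_correlation(Lp, expr_values(tp)[g, ], purity)$pcc,
        numeric(1)),
      p2 = vapply(imm, function(g)
        partial_correlation(S, expr_values(tp)[g, ], purity)$p,
        numeric(1)),
      cor2 = vapply(imm, function(g)
        partial_correlation(S, expr_values(tp)[g, ], purity)$pcc,
        numeric(1)))
    expect_equal(pt$null_scores[b], wpc_score(terms, p_floor = 1e-3),
                 tolerance = 1e-9)
  }
})

test_that("permutation p-values are uniform on exchangeable null data", {
  cohort <- generate_null_cohort(63, 120, seed = 81)
  cls <- gene_classes(cohort)
  lncs <- names(cls)[cls == "lncRNA"][1:10]
  ssgs <- names(cls)[cls == "SSG"][1:10]
  imm <- names(cls)[cls == "immune"][1:10]
  beta <- setNames(rep(1, 10), imm)
  ps <- as.vector(vapply(seq_along(lncs), function(i) {
    vapply(seq_along(ssgs), function(j) {
      permutation_test(cohort, lncs[i], ssgs[j], beta, n_perm = 100,
                       seed = 1000 + 10 * i + j)$perm_p
    }, numeric(1))
  }, numeric(10)))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("triplet assembly retains a planted pair among nulls", {
  # LSI: the lncRNA correlates with both partners, so the WPC permutation
  # has power (for a CR collider the lncRNA-immune link is absent by
  # construction and the pair is invisible to this statistic)
  spec <- triplet_spec("LSI", a = 0.8, b = 0.8, noise_sd = 1)
  cfg <- synthetic_cohort_config(300, list(spec), n_null_genes = 30,
                                 seed = 91)
  res <- generate_cohort(cfg)
  gmt <- synth_gene_sets(res$cohort,
                         planted_immune = res$provenance$immune,
                         n_sets = 2, set_size = 4, seed = 92)
  cls <- gene_classes(res$cohort)
  trip <- suppressWarnings(assemble_triplets(
    res$cohort,
    lncRNAs = names(cls)[cls == "lncRNA"],
    ssgs = names(cls)[cls == "SSG"],
    immune_pathways = gmt, n_perm = 200, n_gsea_perm = 100, seed = 93))
  expect_true(any(trip$lncRNA == res$provenance$lncRNA &
                    trip$ssg == res$provenance$ssg))
  expect_true(all(trip$fdr < 0.05))
  expect_equal(trip$wpc, vapply(trip$terms, wpc_score, numeric(1)),
               tolerance = 1e-9)
  expect_true(all(res$provenance$immune %in%
                    trip$immune_genes[trip$lncRNA == res$provenance$lncRNA &
                                        trip$ssg == res$provenance$ssg][[1]]))
})
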