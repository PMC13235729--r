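#' Purity-adjusted partial correlation
#'
#' First-order partial correlation between `x` and `y` controlling for a
#' single covariate (tumour purity):
#' `pcc = (R_xy - R_xp R_yp) / (sqrt(1 - R_xp^2) sqrt(1 - R_yp^2))`,
#' with the p-value from `t = pcc sqrt((n - 3) / (1 - pcc^2))` on `n - 3`
#' degrees of freedom. Equivalent to the Pearson correlation of the OLS
#' residuals of `x ~ covariate` and `y ~ covariate`.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param covariate Numeric covariate vector (not constant).
#' @return One-row tibble: `pcc`, `p`, `n`, `r_xy`, `r_xp`, `r_yp`.
#' @export
partial_correlation <- function(x, y, covariate) {
  n <- length(x)
  if (length(y) != n || length(covariate) != n) {
    abort("`x`, `y` and `covariate` must have equal length.")
  }
  if (n < 4) abort("Need at least 4 observations.")
  if (sd(covariate) == 0) abort("`covariate` must not be constant.")
  r_xy <- cor(x, y)
  r_xp <- cor(x, covariate)
  r_yp <- cor(y, covariate)
  if (abs(r_xp) >= 1 - 1e-12 || abs(r_yp) >= 1 - 1e-12) {
    abort("Degenerate partial correlation: a variable is collinear with the covariate.")
  }
  pcc <- (r_xy - r_xp * r_yp) / (sqrt(1 - r_xp^2) * sqrt(1 - r_yp^2))
  pcc <- min(max(pcc, -1), 1)
  p <- pcor_pvalue(pcc, n)
  tibble(pcc = pcc, p = p, n = n, r_xy = r_xy, r_xp = r_xp, r_yp = r_yp)
}

# t-test p-value for a first-order partial correlation on n - 3 df
pcor_pvalue <- function(pcc, n) {
  pcc <- pmin(pmax(pcc, -1), 1)
  tstat <- pcc * sqrt((n - 3) / pmax(1 - pcc^2, 1e-300))
  2 * pt(-abs(tstat), n - 3)
}

# Partial correlations of one vector against the columns of a matrix,
# controlling for a shared covariate. Returns list(pcc, p).
pcor_vec <- function(x, M, covariate) {
  n <- length(x)
  r_xy <- as.numeric(cor(x, M))
  r_xp <- cor(x, covariate)
  r_yp <- as.numeric(cor(covariate, M))
  pcc <- (r_xy - r_xp * r_yp) / (sqrt(1 - r_xp^2) * sqrt(1 - r_yp^2))
  pcc <- pmin(pmax(pcc, -1), 1)
  list(pcc = pcc, p = pcor_pvalue(pcc, n))
}

#' Weighted partial-correlation (WPC) score
#'
#' Signed evidence that an lncRNA-SSG pair co-regulates a set of immune
#' genes: `WPC = sum_i beta_i (-log10(P_i1) sign(cor_i1)
#' - log10(P_i2) sign(cor_i2))`, where for immune gene `i` the `(1)` terms
#' come from the lncRNA-immune partial correlation and the `(2)` terms from
#' the SSG-immune partial correlation, and `beta_i` is the gene's enrichment
#' weight. P-values of exactly zero (numeric underflow) are floored at
#' `p_floor` with a warning so the score stays finite.
#'
#' @param terms Data frame with columns `beta`, `p1`, `cor1`, `p2`, `cor2`
#'   (one row per immune gene). Zero rows give a score of 0.
#' @param p_floor Floor applied to non-positive p-values.
#' @return A single numeric WPC score.
#' @export
wpc_score <- function(terms, p_floor = 1e-4) {
  terms <- as.data.frame(terms)
  if (nrow(terms) == 0) return(0)
  stopifnot(all(c("beta", "p1", "cor1", "p2", "cor2") %in% names(terms)))
  p1 <- terms$p1
  p2 <- terms$p2
  if (any(p1 <= 0) || any(p2 <= 0)) {
    warn(sprintf("Flooring %d underflowed p-value(s) at %g.",
                 sum(p1 <= 0) + sum(p2 <= 0), p_floor))
    p1 <- pmax(p1, p_floor)
    p2 <- pmax(p2, p_floor)
  }
  sum(terms$beta * (-log10(p1) * sign(terms$cor1)
                    - log10(p2) * sign(terms$cor2)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH adjusted p-values (clipped at 1), via [stats::p.adjust()]
#' after validating the input range.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (FDR), same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}

# Per-gene WPC term table for a pair against a fixed immune-gene matrix.
# L, S: vectors; G: n x m matrix; purity: covariate; beta: named weights.
wpc_terms <- function(L, S, G, purity, beta) {
  t1 <- pcor_vec(L, G, purity)
  t2 <- pcor_vec(S, G, purity)
  tibble(gene_id = colnames(G), beta = unname(beta[colnames(G)]),
         cor1 = t1$pcc, p1 = t1$p, cor2 = t2$pcc, p2 = t2$p)
}

#' Permutation null for a pair's WPC score
#'
#' Recomputes the WPC score after shuffling the lncRNA's sample labels
#' (breaking the lncRNA-SSG and lncRNA-immune links while keeping SSG,
#' immune and purity aligned), with the immune-gene weights `beta` held
#' fixed. The empirical p-value follows the raw exceedance formula
#' `p = N / n_perm`, where `N` counts permutations with
#' `|null WPC| >= |observed WPC|` (two-sided, since the score is signed);
#' it therefore takes values in `{0, 1/n_perm, ..., 1}`, and a reported 0
#' means "below 1/n_perm".
#'
#' @param cohort An [expression_cohort()] containing the pair; only tumour
#'   samples with purity are used.
#' @param lncRNA,ssg Gene ids of the pair.
#' @param beta Named numeric vector of immune-gene enrichment weights
#'   (genes with weight 0 are ignored), e.g. from [enrichment_weights()].
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param p_floor Passed to [wpc_score()]; defaults to `1 / (10 * n_perm)`.
#' @return List of class `wpc_permutation`: `observed`, `perm_p`,
#'   `null_scores`, `n_perm`, `terms` (the observed per-gene term table).
#' @export
permutation_test <- function(cohort, lncRNA, ssg, beta, n_perm = 1000,
                             seed = 1, p_floor = NULL) {
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  p_floor <- p_floor %||% (1 / (10 * n_perm))
  tp <- tumor_purity_samples(cohort)
  genes <- names(beta)[beta != 0]
  L <- tp$values[lncRNA, ]
  S <- tp$values[ssg, ]
  purity <- tp$samples$purity
  n <- length(L)

  if (length(genes) == 0) {
    return(structure(list(observed = 0, perm_p = 1,
                          null_scores = rep(0, n_perm), n_perm = n_perm,
                          terms = tibble(gene_id = character(),
                                         beta = numeric(), cor1 = numeric(),
                                         p1 = numeric(), cor2 = numeric(),
                                         p2 = numeric())),
                     class = "wpc_permutation"))
  }
  G <- t(tp$values[genes, , drop = FALSE])
  terms <- wpc_terms(L, S, G, purity, beta)
  observed <- wpc_score(terms, p_floor = p_floor)

  # SSG-side contribution is invariant under L-permutations
  t2 <- pcor_vec(S, G, purity)
  p2f <- ifelse(t2$p <= 0, p_floor, t2$p)  # floor only on underflow
  term2 <- sum(beta[genes] * (-log10(p2f)) * sign(t2$pcc))

  Gs <- scale(G)
  ps <- as.numeric(scale(purity))
  r_yp <- as.numeric(cor(purity, G))
  Ls <- as.numeric(scale(L))
  perm_mat <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) Ls[sample.int(n)], numeric(n))
  })
  R_xy <- crossprod(Gs, perm_mat) / (n - 1)              # m x n_perm
  R_xp <- as.numeric(crossprod(ps, perm_mat)) / (n - 1)  # n_perm
  denom <- outer(sqrt(1 - r_yp^2), sqrt(1 - R_xp^2))
  pcc1 <- (R_xy - outer(r_yp, R_xp)) / denom
  pcc1 <- pmin(pmax(pcc1, -1), 1)
  p1 <- pcor_pvalue(pcc1, n)
  p1[p1 <= 0] <- p_floor
  null_scores <- as.numeric(
    crossprod(beta[genes], -log10(p1) * sign(pcc1))) + term2
  perm_p <- sum(abs(null_scores) >= abs(observed)) / n_perm
  structure(list(observed = observed, perm_p = perm_p,
                 null_scores = null_scores, n_perm = n_perm, terms = terms),
            class = "wpc_permutation")
}

#' @export
print.wpc_permutation <- function(x, ...) {
  annot <- if (x$perm_p == 0) sprintf(" (< %g)", 1 / x$n_perm) else ""
  cat(sprintf("<wpc_permutation> observed WPC = %.4g, p = %g%s (%d permutations)\n",
              x$observed, x$perm_p, annot, x$n_perm))
  invisible(x)
}

#' Assemble candidate core regulatory triplets
#'
#' For every prioritised lncRNA x SSG pair: computes pair-specific immune
#' enrichment weights ([enrichment_weights()]), the WPC score, and its
#' permutation p-value ([permutation_test()]); then adjusts the p-values by
#' BH across all pairs and retains pairs with `fdr < fdr_threshold`. The
#' immune genes with non-zero weight become the triplet's immune partners.
#'
#' @param cohort An [expression_cohort()].
#' @param lncRNAs,ssgs Character vectors of candidate lncRNAs and SSGs
#'   (e.g. from [pagerank_prioritize()] / [select_top_fraction()]).
#' @param immune_pathways A [gene_set_collection()] of immune pathways.
#' @param immune_genes Immune genes to score; defaults to all immune-classed
#'   cohort genes.
#' @param fdr_threshold Retention threshold on the BH-adjusted permutation
#'   p-values.
#' @param n_perm Permutations per pair.
#' @param n_gsea_perm Gene-set permutations inside the enrichment step.
#' @param seed Integer seed; each pair uses a fixed offset of it.
#' @return Tibble with one row per retained pair: `lncRNA`, `ssg`,
#'   `immune_genes` (list-column), `n_immune`, `wpc`, `perm_p`, `fdr`, and
#'   `terms` (list-column of per-gene term tables). The unfiltered table is
#'   attached as attribute `"all_pairs"`.
#' @export
assemble_triplets <- function(cohort, lncRNAs, ssgs, immune_pathways,
                              immune_genes = NULL, fdr_threshold = 0.05,
                              n_perm = 1000, n_gsea_perm = 200, seed = 1) {
  lncRNAs <- unique(lncRNAs)
  ssgs <- unique(ssgs)
  if (length(lncRNAs) == 0 || length(ssgs) == 0) {
    abort("Need at least one candidate lncRNA and one SSG.")
  }
  pairs <- tidyr::expand_grid(lncRNA = lncRNAs, ssg = ssgs)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ln <- pairs$lncRNA[i]
    sg <- pairs$ssg[i]
    ew <- enrichment_weights(cohort, ln, sg, immune_pathways,
                             immune_genes = immune_genes,
                             n_perm = n_gsea_perm, seed = seed + 7L * i)
    pt <- permutation_test(cohort, ln, sg, ew$beta, n_perm = n_perm,
                           seed = seed + 13L * i)
    rows[[i]] <- tibble(
      lncRNA = ln, ssg = sg,
      immune_genes = list(names(ew$beta)[ew$beta != 0]),
      n_immune = sum(ew$beta != 0),
      wpc = pt$observed, perm_p = pt$perm_p,
      terms = list(pt$terms))
  }
  all_pairs <- bind_rows(rows)
  all_pairs$fdr <- bh_adjust(all_pairs$perm_p)
  out <- all_pairs |>
    filter(.data$fdr < fdr_threshold) |>
    arrange(.data$fdr, desc(abs(.data$wpc)), .data$lncRNA, .data$ssg) |>
    select("lncRNA", "ssg", "immune_genes", "n_immune", "wpc",
           "perm_p", "fdr", "terms")
  if (nrow(out) == 0) {
    warn("No lncRNA-SSG pair passed the FDR threshold.")
  }
  attr(out, "all_pairs") <- all_pairs
  out
}
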