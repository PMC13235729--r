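#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Standard GSEA running-sum statistic with weight exponent 1: walking down
#' the ranked list, hits increment the running sum by their absolute metric
#' (normalised by the total absolute metric of the set) and misses decrement
#' it by `1 / (N - N_hit)`; the enrichment score is the maximum deviation
#' from zero. When every hit has metric 0 the hits fall back to equal
#' increments.
#'
#' @param metric Named numeric vector of ranking metrics (names are gene
#'   ids); internally sorted in decreasing order, ties broken by id.
#' @param set Character vector of member genes.
#' @return The signed enrichment score in \[-1, 1\].
#' @export
gsea_enrichment_score <- function(metric, set) {
  ord <- order(-metric, names(metric))
  m <- metric[ord]
  hit <- names(m) %in% set
  if (!any(hit)) return(0)
  if (all(hit)) abort("Gene set covers the whole ranked list.")
  nr <- sum(abs(m[hit]))
  inc <- if (nr > 0) abs(m) / nr else rep(1 / sum(hit), length(m))
  steps <- ifelse(hit, inc, -1 / (length(m) - sum(hit)))
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Pair-specific immune-gene enrichment weights
#'
#' Computes the GSEA-derived weights `beta_i` entering the WPC score for one
#' lncRNA-SSG pair. Immune genes are ranked by the mean of their two
#' absolute purity-adjusted partial correlations (with the lncRNA and with
#' the SSG); each immune pathway is scored with the weighted running-sum
#' statistic ([gsea_enrichment_score()]) and assigned a gene-permutation
#' p-value (random same-size gene sets drawn from the ranked universe,
#' sign-matched exceedance). A gene's weight is the enrichment score of the
#' best-ranked pathway containing it (smallest permutation p, ties broken by
#' larger absolute ES); genes in no pathway get weight 0. Setting
#' `alpha < 1` additionally requires that pathway to be significantly
#' enriched (`p < alpha`), zeroing the weights of genes found only in
#' non-enriched pathways. The gate is off by default because the
#' gene-permutation p of a small immune universe is floor-limited near
#' `set size / universe size`; the downstream permutation null on the WPC
#' score provides the error control either way.
#'
#' @param cohort An [expression_cohort()]; only tumour samples with purity
#'   are used.
#' @param lncRNA,ssg Gene ids of the pair.
#' @param immune_pathways A [gene_set_collection()] (pathways with no gene
#'   in the cohort are skipped with a warning).
#' @param immune_genes Immune genes to rank; defaults to all immune-classed
#'   cohort genes (the pair itself is excluded).
#' @param n_perm Number of random gene sets per pathway.
#' @param alpha Optional pathway significance gate in (0, 1\]; 1 disables it.
#' @param seed Integer seed.
#' @return List of class `enrichment_weights`: `beta` (named weights over
#'   `immune_genes`), `pathway_es` (tibble: `pathway`, `size`, `es`, `p`),
#'   `ranking` (tibble: `gene_id`, `metric`), `ranking_used` (description).
#' @export
enrichment_weights <- function(cohort, lncRNA, ssg, immune_pathways,
                               immune_genes = NULL, n_perm = 1000,
                               alpha = 1, seed = 1) {
  stopifnot(inherits(immune_pathways, "gene_set_collection"))
  if (length(immune_pathways$sets) < 1) {
    abort("Need at least one immune pathway.")
  }
  cls <- gene_classes(cohort)
  immune_genes <- immune_genes %||% names(cls)[cls == "immune"]
  immune_genes <- setdiff(immune_genes, c(lncRNA, ssg))
  if (length(immune_genes) == 0) abort("No immune genes present in cohort.")
  tp <- tumor_purity_samples(cohort)
  L <- tp$values[lncRNA, ]
  S <- tp$values[ssg, ]
  G <- t(tp$values[immune_genes, , drop = FALSE])
  purity <- tp$samples$purity
  a1 <- abs(pcor_vec(L, G, purity)$pcc)
  a2 <- abs(pcor_vec(S, G, purity)$pcc)
  metric <- setNames((a1 + a2) / 2, immune_genes)

  beta <- setNames(rep(0, length(immune_genes)), immune_genes)
  es_rows <- list()
  best_p <- setNames(rep(Inf, length(immune_genes)), immune_genes)
  withr::with_seed(seed, {
    for (pw in names(immune_pathways$sets)) {
      members <- intersect(immune_pathways$sets[[pw]], immune_genes)
      if (length(members) == 0) {
        warn(sprintf("Pathway '%s' has no genes in the cohort; skipped.", pw))
        next
      }
      if (length(members) == length(immune_genes)) {
        warn(sprintf("Pathway '%s' covers all ranked genes; skipped.", pw))
        next
      }
      es <- gsea_enrichment_score(metric, members)
      null_es <- vapply(seq_len(n_perm), function(b) {
        gsea_enrichment_score(metric,
                              sample(immune_genes, length(members)))
      }, numeric(1))
      p <- if (es >= 0) {
        mean(null_es >= es)
      } else {
        mean(null_es <= es)
      }
      es_rows[[pw]] <- tibble(pathway = pw, size = length(members),
                              es = es, p = p)
      if (alpha >= 1 || p < alpha) {
        upd <- members[p < best_p[members] |
                         (p == best_p[members] & abs(es) > abs(beta[members]))]
        beta[upd] <- es
        best_p[upd] <- p
      }
    }
  })
  pathway_es <- if (length(es_rows) > 0) bind_rows(es_rows) else
    tibble(pathway = character(), size = integer(), es = numeric(),
           p = numeric())
  structure(
    list(beta = beta, pathway_es = pathway_es,
         ranking = tibble(gene_id = names(metric),
                          metric = unname(metric)) |>
           arrange(desc(.data$metric), .data$gene_id),
         ranking_used = "mean absolute purity-adjusted partial correlation with the lncRNA and the SSG"),
    class = "enrichment_weights")
}

#' @export
print.enrichment_weights <- function(x, ...) {
  cat(sprintf("<enrichment_weights> %d immune genes, %d pathway(s), %d with non-zero weight\n",
              length(x$beta), nrow(x$pathway_es), sum(x$beta != 0)))
  invisible(x)
}
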