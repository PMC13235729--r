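#' Tumour-versus-normal differential expression
#'
#' Per-gene Welch two-sample t-test on the log2 scale, with the log2 fold
#' change computed as `mean(tumor) - mean(normal)` and Benjamini-Hochberg
#' FDR. A gene passes when `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold` jointly.
#'
#' @param cohort An [expression_cohort()] with both `tumor` and `normal`
#'   samples (at least 2 each).
#' @param lfc_threshold Absolute log2 fold-change threshold (strict `>`).
#' @param fdr_threshold FDR threshold (strict `<`).
#' @return Tibble with columns `gene_id`, `class`, `log2fc`, `p`, `fdr`,
#'   `passes`.
#' @export
differential_expression <- function(cohort, lfc_threshold = 1,
                                    fdr_threshold = 0.05) {
  cond <- cohort$samples$condition
  tum <- which(!is.na(cond) & cond == "tumor")
  nrm <- which(!is.na(cond) & cond == "normal")
  if (length(tum) < 2 || length(nrm) < 2) {
    abort("Need at least 2 tumor and 2 normal samples.")
  }
  x <- cohort$values[, tum, drop = FALSE]
  y <- cohort$values[, nrm, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- ifelse(se2 > 0, lfc / sqrt(se2), ifelse(lfc == 0, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- 2 * pt(-abs(tstat), df)
  p[!is.finite(tstat)] <- 0
  fdr <- p.adjust(p, method = "BH")
  tibble(gene_id = gene_ids(cohort), class = cohort$genes$class,
         log2fc = unname(lfc), p = unname(p), fdr = unname(fdr),
         passes = abs(lfc) > lfc_threshold & fdr < fdr_threshold)
}

#' Random walk with restart on a weighted network
#'
#' Iterates `p(t+1) = (1 - r) A p(t) + r p(0)` with `A` the column-stochastic
#' transition operator of the network and `p(0)` uniform over the seed
#' nodes, until the L1 change drops below `tol`. At convergence the scores
#' equal the closed form `r (I - (1 - r) A)^{-1} p(0)`.
#'
#' @param network A [weighted_network()].
#' @param seeds Non-empty character vector of seed nodes (must be in the
#'   network).
#' @param r Restart probability in (0, 1\].
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum number of iterations.
#' @return A `propagation_result`: tibble (`node`, `score`) sorted by
#'   decreasing score then node id, with attributes `restart`, `seeds`,
#'   `iterations`, `residual`. Scores are non-negative and sum to 1.
#' @export
rwr <- function(network, seeds, r = 0.85, tol = 1e-10, max_iter = 1000) {
  stopifnot(r > 0, r <= 1)
  seeds <- unique(seeds)
  if (length(seeds) == 0) abort("`seeds` must be non-empty.")
  missing <- setdiff(seeds, network$nodes)
  if (length(missing) > 0) {
    abort(paste0("Seed node(s) not in network: ", toString(missing)))
  }
  A <- transition_matrix(network)
  n <- length(network$nodes)
  p0 <- setNames(numeric(n), network$nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  iter <- 0L
  residual <- Inf
  while (iter < max_iter) {
    p_new <- (1 - r) * as.numeric(A %*% p) + r * p0
    residual <- sum(abs(p_new - p))
    p <- setNames(p_new, network$nodes)
    iter <- iter + 1L
    if (residual < tol) break
  }
  if (residual >= tol) {
    warn(sprintf("RWR did not reach tol=%.1e in %d iterations (residual %.1e).",
                 tol, max_iter, residual))
  }
  out <- tibble(node = network$nodes, score = unname(p)) |>
    arrange(desc(.data$score), .data$node)
  structure(out, class = c("propagation_result", class(out)),
            restart = r, seeds = seeds, iterations = iter,
            residual = residual)
}

#' Select the top-scoring fraction of propagated nodes
#'
#' Returns the `ceiling(fraction * n_eligible)` highest-scoring nodes of a
#' propagation result (default: the top 5%). Seeds are excluded from the
#' eligible set by default; ties at the cutoff are broken lexicographically
#' by node id.
#'
#' @param result A `propagation_result` from [rwr()].
#' @param fraction Fraction in (0, 1\].
#' @param exclude_seeds Drop seed nodes before ranking?
#' @return Character vector of selected node ids, ranked.
#' @export
select_top_fraction <- function(result, fraction = 0.05,
                                exclude_seeds = TRUE) {
  stopifnot(fraction > 0, fraction <= 1)
  nodes <- result$node
  scores <- result$score
  if (exclude_seeds) {
    keep <- !nodes %in% attr(result, "seeds")
    nodes <- nodes[keep]
    scores <- scores[keep]
  }
  k <- ceiling(fraction * length(nodes))
  ord <- order(-scores, nodes)
  nodes[ord][seq_len(min(k, length(nodes)))]
}

#' Build a co-expression network among screened genes
#'
#' Computes all pairwise Pearson correlations among the differentially
#' expressed genes of the requested classes (tumour samples when condition
#' labels exist) and keeps edges with `|r| >= min_abs_r` and BH-adjusted
#' correlation-test p below `fdr_threshold`. Edge weight is `|r|`; the
#' signed correlation is retained in the `signed_r` edge column. Genes with
#' constant expression are dropped with a warning. All considered genes are
#' kept as network nodes, so unconnected genes appear as isolated nodes.
#'
#' @param cohort An [expression_cohort()] (>= 10 usable samples).
#' @param de Optional tibble from [differential_expression()]; when given,
#'   only its `passes` genes enter the network. When `NULL`, all cohort
#'   genes of the requested classes are used.
#' @param classes Gene classes to include.
#' @param min_abs_r Absolute-correlation threshold.
#' @param fdr_threshold BH-adjusted p threshold.
#' @return A [weighted_network()].
#' @export
build_coexpression_network <- function(cohort, de = NULL,
                                       classes = c("lncRNA", "immune", "SSG"),
                                       min_abs_r = 0.3,
                                       fdr_threshold = 0.05) {
  cls <- gene_classes(cohort)
  genes <- names(cls)[cls %in% classes]
  if (!is.null(de)) {
    genes <- intersect(genes, de$gene_id[de$passes])
  }
  if (length(genes) < 2) {
    warn("Fewer than 2 eligible genes; returning an empty network.")
    return(weighted_network(tibble(from = character(), to = character(),
                                   weight = numeric()), nodes = genes))
  }
  cond <- cohort$samples$condition
  use <- if (any(!is.na(cond) & cond == "tumor")) {
    which(!is.na(cond) & cond == "tumor")
  } else {
    seq_along(cond)
  }
  if (length(use) < 10) abort("Need at least 10 samples for co-expression.")
  X <- t(cohort$values[genes, use, drop = FALSE])
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("Skipping constant gene(s): ",
                toString(head(genes[sds == 0], 5))))
    genes <- genes[sds > 0]
    X <- X[, genes, drop = FALSE]
  }
  if (length(genes) < 2) {
    return(weighted_network(tibble(from = character(), to = character(),
                                   weight = numeric()), nodes = genes))
  }
  R <- cor(X)
  n <- nrow(X)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]
  r_t <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_t * sqrt((n - 2) / (1 - r_t^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  fdr <- p.adjust(p, method = "BH")
  keep <- abs(r) >= min_abs_r & fdr < fdr_threshold
  edges <- tibble(from = genes[ut[, 1]], to = genes[ut[, 2]],
                  weight = abs(r), signed_r = r)[keep, ]
  weighted_network(edges, nodes = genes)
}

#' Prioritise lncRNAs and immune genes around SSGs by personalised PageRank
#'
#' Runs personalised PageRank on the co-expression network with the
#' personalisation mass uniform over the SSG seed set and zero elsewhere
#' (computed as [rwr()] with restart `1 - damping` on the same
#' column-stochastic operator), then returns the `top_k` lncRNAs and
#' `top_k` immune genes by score (fewer when a class is smaller). Ties are
#' broken lexicographically by gene id.
#'
#' @param network A [weighted_network()] (typically from
#'   [build_coexpression_network()]).
#' @param ssg_seeds Non-empty character vector of SSG nodes.
#' @param gene_class Named character vector of gene classes covering the
#'   network nodes (nodes without an entry are treated as `"other"`).
#' @param top_k Number of genes to keep per class (default 200).
#' @param damping PageRank damping factor.
#' @return Tibble (`gene_id`, `class`, `score`, `rank`) restricted to the
#'   `lncRNA` and `immune` classes, ranked within class.
#' @export
pagerank_prioritize <- function(network, ssg_seeds, gene_class,
                                top_k = 200, damping = 0.85) {
  res <- rwr(network, seeds = ssg_seeds, r = 1 - damping)
  cls <- setNames(rep("other", length(network$nodes)), network$nodes)
  known <- intersect(names(gene_class), network$nodes)
  cls[known] <- gene_class[known]
  out <- tibble(gene_id = res$node, class = unname(cls[res$node]),
                score = res$score) |>
    filter(.data$class %in% c("lncRNA", "immune")) |>
    arrange(.data$class, desc(.data$score), .data$gene_id) |>
    group_by(.data$class) |>
    mutate(rank = row_number()) |>
    slice_head(n = top_k) |>
    ungroup()
  if (!any(out$class == "lncRNA")) {
    warn("No lncRNA nodes in the network; lncRNA list is empty.")
  }
  if (!any(out$class == "immune")) {
    warn("No immune nodes in the network; immune list is empty.")
  }
  out
}
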