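#' Construct an undirected weighted network
#'
#' The container used for both the protein-protein interaction network and
#' the co-expression network. Edges are undirected with strictly positive
#' weights, stored once per unordered pair; duplicated pairs keep the
#' maximum weight. Extra edge columns (e.g. `signed_r` from the
#' co-expression builder) are carried along.
#'
#' @param edges Data frame with columns `from`, `to`, `weight` (> 0).
#' @param nodes Optional character vector of node ids; defaults to the nodes
#'   appearing in `edges`. Extra ids become isolated nodes.
#' @return An object of class `weighted_network`: list with `nodes`
#'   (character) and `edges` (tibble).
#' @export
weighted_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  if (nrow(edges) > 0) {
    if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
    if (any(edges$weight <= 0)) abort("Edge weights must be positive.")
    # canonical unordered orientation, keep max weight per pair
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges |>
      arrange(.data$from, .data$to, desc(.data$weight)) |>
      distinct(.data$from, .data$to, .keep_all = TRUE)
  }
  nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Column-stochastic transition operator of a network
#'
#' Normalises the symmetric weighted adjacency matrix column-wise so that
#' `A[i, j]` is the probability of stepping from node `j` to node `i` in a
#' random walk. Isolated nodes receive an identity self-transition column so
#' the operator stays stochastic (no probability leakage).
#'
#' @param network A [weighted_network()].
#' @return A dense column-stochastic matrix with node dimnames.
#' @export
transition_matrix <- function(network) {
  n <- length(network$nodes)
  A <- matrix(0, n, n, dimnames = list(network$nodes, network$nodes))
  if (nrow(network$edges) > 0) {
    i <- match(network$edges$from, network$nodes)
    j <- match(network$edges$to, network$nodes)
    w <- network$edges$weight
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  deg <- colSums(A)
  isolated <- deg == 0
  if (any(isolated)) {
    A[cbind(which(isolated), which(isolated))] <- 1
    deg[isolated] <- 1
  }
  sweep(A, 2, deg, "/")
}

#' Convert a weighted network to an igraph object
#'
#' @param network A [weighted_network()].
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(network) {
  igraph::graph_from_data_frame(as.data.frame(network$edges),
                                directed = FALSE,
                                vertices = network$nodes)
}
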