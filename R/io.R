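#' Read an expression cohort from TSV files
#'
#' Expression is a TSV with a header row of sample ids and gene ids in the
#' first column. Gene classes come from a two-column TSV (`gene`, `class`);
#' genes absent from it are classed `"other"`. Optional sample metadata is a
#' TSV with columns `sample` and any of `condition`, `purity`, `time`,
#' `event`.
#'
#' @param path Path to the expression TSV.
#' @param class_path Optional path to the gene-class TSV.
#' @param meta_path Optional path to the sample-metadata TSV.
#' @return An [expression_cohort()].
#' @export
read_expression <- function(path, class_path = NULL, meta_path = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("Expression TSV needs a gene column plus samples.")
  genes <- raw[[1]]
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    abort(paste0("Duplicate gene ids in ", path, ": ",
                 toString(head(dups, 5))))
  }
  samples <- names(raw)[-1]
  num <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw)))
  )
  if (nrow(raw) == 1) num <- matrix(num, nrow = 1)
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Non-numeric or missing expression value for gene '%s', sample '%s'.",
      genes[idx[1]], samples[idx[2]]))
  }
  dimnames(num) <- list(genes, samples)

  gene_class <- NULL
  if (!is.null(class_path)) {
    cls <- readr::read_tsv(class_path,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    if (ncol(cls) < 2) abort("Gene-class TSV must have two columns.")
    # tolerate a headerless two-column file
    if (!all(c("gene", "class") %in% names(cls)) &&
        names(cls)[2] %in% GENE_CLASSES) {
      cls <- rbind(setNames(as.list(names(cls)), c("gene", "class")),
                   setNames(cls, c("gene", "class")))
    }
    names(cls)[1:2] <- c("gene", "class")
    gene_class <- setNames(cls$class, cls$gene)
  }

  condition <- purity <- surv <- NULL
  if (!is.null(meta_path)) {
    meta <- readr::read_tsv(meta_path, col_types = readr::cols(),
                            progress = FALSE)
    if (!"sample" %in% names(meta)) abort("Metadata TSV needs a 'sample' column.")
    if ("condition" %in% names(meta)) {
      condition <- setNames(as.character(meta$condition), meta$sample)
    }
    if ("purity" %in% names(meta)) {
      purity <- setNames(as.numeric(meta$purity), meta$sample)
    }
    if (all(c("time", "event") %in% names(meta))) {
      surv <- data.frame(sample = meta$sample, time = meta$time,
                         event = meta$event)
    }
  }
  expression_cohort(num, gene_class = gene_class, condition = condition,
                    purity = purity, survival = surv)
}

#' Write a cohort back to TSV files
#'
#' Inverse of [read_expression()]; used by the CLI and for round-trips.
#'
#' @param cohort An [expression_cohort()].
#' @param path Expression TSV path.
#' @param class_path,meta_path Optional output paths for classes/metadata.
#' @return `path`, invisibly.
#' @export
write_expression <- function(cohort, path, class_path = NULL,
                             meta_path = NULL) {
  df <- as.data.frame(cohort$values)
  df <- cbind(gene = rownames(cohort$values), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  if (!is.null(class_path)) {
    readr::write_tsv(
      tibble(gene = cohort$genes$gene_id, class = cohort$genes$class),
      class_path, progress = FALSE)
  }
  if (!is.null(meta_path)) {
    smp <- cohort$samples
    readr::write_tsv(
      tibble(sample = smp$sample_id, condition = smp$condition,
             purity = smp$purity, time = smp$time, event = smp$event),
      meta_path, progress = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Duplicate members within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields.", i))
    }
    nm <- fields[[1]]
    sets[[nm]] <- unique(fields[-(1:2)])
    desc[[nm]] <- fields[[2]]
  }
  gene_set_collection(sets, desc)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member genes).
#' @param description Optional named character vector of descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets))) {
      abort("Gene-set names must be unique and non-empty.")
    }
    if (any(lengths(sets) == 0)) abort("Every gene set must be non-empty.")
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  structure(list(sets = sets,
                 description = description %||%
                   setNames(rep("", length(sets)), names(sets))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets", length(x$sets)))
  if (length(x$sets) > 0) {
    cat(sprintf(" (sizes %d-%d)", min(lengths(x$sets)), max(lengths(x$sets))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read a STRING-style weighted edge list
#'
#' Rows are `node1`, `node2`, `combined_score`. Edges with score strictly
#' greater than `min_score` are retained and rescaled to weights
#' `score / max_score`; the graph is undirected, self-loop rows are skipped
#' with a warning and duplicated pairs keep the maximum weight.
#'
#' @param path Path to a 3-column TSV (a header row is detected and skipped).
#' @param min_score Retention threshold on the combined score (strict `>`).
#' @param max_score Score ceiling used to rescale weights into (0, 1\].
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path, min_score = 700, max_score = 1000) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) > 0 && ncol(raw) < 3) {
    abort("Edge list must have 3 columns: node1, node2, score.")
  }
  if (nrow(raw) > 0 &&
      is.na(suppressWarnings(as.numeric(raw[[3]][1])))) {
    raw <- raw[-1, , drop = FALSE]  # header row
  }
  if (nrow(raw) == 0) {
    warn("Edge list is empty; returning an empty network.")
    return(weighted_network(tibble(from = character(), to = character(),
                                   weight = numeric())))
  }
  score <- suppressWarnings(as.numeric(raw[[3]]))
  if (anyNA(score)) {
    abort(sprintf("Non-numeric score at edge-list row %d.",
                  which(is.na(score))[1]))
  }
  edges <- tibble(from = raw[[1]], to = raw[[2]], score = score)
  loops <- edges$from == edges$to
  if (any(loops)) {
    warn(sprintf("Skipping %d self-loop row(s).", sum(loops)))
    edges <- edges[!loops, ]
  }
  edges <- edges[edges$score > min_score, ]
  if (nrow(edges) == 0) {
    warn("No edges exceed `min_score`; returning an empty network.")
    return(weighted_network(tibble(from = character(), to = character(),
                                   weight = numeric())))
  }
  edges$weight <- edges$score / max_score
  weighted_network(edges[c("from", "to", "weight")])
}

#' Write a network as an edge list or GraphML
#'
#' @param network A [weighted_network()].
#' @param path Output path.
#' @param max_score Rescaling factor so the written scores invert the
#'   `weight = score / max_score` convention of [read_edge_list()].
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path, max_score = 1000) {
  readr::write_tsv(
    tibble(node1 = network$edges$from, node2 = network$edges$to,
           score = network$edges$weight * max_score),
    path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
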