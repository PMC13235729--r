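#' Discretise a vector into equiprobable quantile bins
#'
#' Assigns each value a 0-based bin label using the inner quantiles of the
#' empirical distribution as cut points; ties at a cut point go to the lower
#' bin, so heavily tied values always share a bin and bin sizes differ by at
#' most the number of tied values.
#'
#' @param values Numeric vector of length >= `n_bins`, not constant.
#' @param n_bins Number of bins (default 5 equiprobable bins).
#' @return Integer labels in `0:(n_bins - 1)`.
#' @export
#' @examples
#' discretize_quantile(1:10, 5)  # 0 0 1 1 2 2 3 3 4 4
discretize_quantile <- function(values, n_bins = 5) {
  stopifnot(n_bins >= 1)
  if (length(values) < n_bins) abort("Need at least `n_bins` values.")
  if (n_bins == 1) return(rep(0L, length(values)))
  if (max(values) == min(values)) {
    abort("Constant vector: no equiprobable partition exists.")
  }
  cuts <- quantile(values, probs = seq_len(n_bins - 1) / n_bins,
                   names = FALSE)
  labels <- vapply(values, function(v) sum(v > cuts), numeric(1))
  as.integer(labels)
}

# MI in nats from a contingency table of counts (0 log 0 := 0).
mi_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  pr <- rowSums(counts) / n
  pc <- colSums(counts) / n
  nz <- which(counts > 0, arr.ind = TRUE)
  p <- counts[nz] / n
  sum(p * log(p / (pr[nz[, 1]] * pc[nz[, 2]])))
}

# Cross-tabulate two small non-negative integer label vectors quickly.
label_table <- function(x, z) {
  kx <- max(x) + 1L
  kz <- max(z) + 1L
  matrix(tabulate(x * kz + z + 1L, nbins = kx * kz),
         nrow = kx, byrow = TRUE)
}

#' Plug-in mutual information of two label vectors
#'
#' Empirical (maximum-likelihood) estimate in nats,
#' `sum p(x, z) ln( p(x, z) / (p(x) p(z)) )`, from the joint contingency
#' table. Non-negative, symmetric, and bounded by `ln(K)` for `K` bins.
#'
#' @param x_labels,z_labels Equal-length non-negative integer label vectors
#'   (e.g. from [discretize_quantile()]).
#' @param correction `"none"` (plug-in, the default) or `"miller-madow"`,
#'   which subtracts the first-order bias
#'   `(m_xz - m_x - m_z + 1) / (2n)` with `m_*` the occupied cell counts.
#' @return MI estimate in nats.
#' @export
mutual_information <- function(x_labels, z_labels,
                               correction = c("none", "miller-madow")) {
  if (length(x_labels) != length(z_labels)) {
    abort("Label vectors must have equal length.")
  }
  correction <- match.arg(correction)
  counts <- label_table(as.integer(x_labels), as.integer(z_labels))
  mi <- mi_from_counts(counts)
  if (correction == "miller-madow") {
    n <- sum(counts)
    mi <- mi - (sum(counts > 0) - sum(rowSums(counts) > 0) -
                  sum(colSums(counts) > 0) + 1) / (2 * n)
  }
  mi
}

#' Plug-in conditional mutual information
#'
#' `I(X; Z | Y) = sum_y p(y) I(X; Z | Y = y)`: the stratum-weighted plug-in
#' MI within each level of the conditioning labels. In nats, non-negative.
#'
#' @param x_labels,z_labels,y_labels Equal-length non-negative integer label
#'   vectors; `y_labels` is the conditioning variable.
#' @param correction As in [mutual_information()], applied per stratum.
#' @return CMI estimate in nats.
#' @export
conditional_mutual_information <- function(x_labels, z_labels, y_labels,
                                           correction = c("none",
                                                          "miller-madow")) {
  n <- length(x_labels)
  if (length(z_labels) != n || length(y_labels) != n) {
    abort("Label vectors must have equal length.")
  }
  correction <- match.arg(correction)
  x <- as.integer(x_labels)
  z <- as.integer(z_labels)
  y <- as.integer(y_labels)
  out <- 0
  for (lev in unique(y)) {
    idx <- y == lev
    w <- sum(idx) / n
    out <- out + w * mutual_information(x[idx], z[idx],
                                        correction = correction)
  }
  out
}

#' Bootstrap stability of a triplet's information dependencies
#'
#' Quantifies whether the immune gene strengthens the lncRNA-SSG dependence.
#' For each of `B` bootstrap replicates the samples are resampled with
#' replacement, each variable is re-discretised into `n_bins` equiprobable
#' bins within the replicate, and the plug-in MI `I_b(X; Z)` and CMI
#' `I_b(X; Z | Y)` are computed with `X` the lncRNA, `Y` the immune gene and
#' `Z` the SSG. The stability probabilities are the fractions of replicates
#' exceeding the information threshold:
#' `S_pair = mean(I_b(X; Z) > theta)`,
#' `S_triplet = mean(I_b(X; Z | Y) > theta)`, and
#' `Delta S = S_triplet - S_pair`. Replicates in which a resampled variable
#' is constant are redrawn (counted once, reported via a message).
#'
#' @param L,S,I Numeric expression vectors (lncRNA, SSG, immune gene) of
#'   equal length `n >= 25`.
#' @param B Number of bootstrap replicates (default 200).
#' @param theta Information threshold in nats (default 0.2).
#' @param n_bins Number of equiprobable bins (default 5).
#' @param correction MI/CMI estimator: `"none"` (plug-in, the default) or
#'   `"miller-madow"`. Note that on bootstrap resamples even the corrected
#'   estimator retains upward bias from duplicated draws, which inflates CMI
#'   (and hence `S_triplet`) relative to MI at small `n`.
#' @param seed Integer seed; results are bit-identical for a fixed seed.
#' @return One-row tibble of class `stability_result`: `s_pair`,
#'   `s_triplet`, `delta_s`, `B`, `theta`, `n_bins`, `seed`, with the
#'   per-replicate MI and CMI vectors attached as attributes `"mi"` and
#'   `"cmi"`.
#' @export
bootstrap_stability <- function(L, S, I, B = 200, theta = 0.2, n_bins = 5,
                                correction = c("none", "miller-madow"),
                                seed = 1) {
  correction <- match.arg(correction)
  n <- length(L)
  if (length(S) != n || length(I) != n) abort("Vectors must have equal length.")
  if (n < 25) abort("Need at least 25 samples.")
  mi_b <- numeric(B)
  cmi_b <- numeric(B)
  redraws <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      for (try in 1:100) {
        idx <- sample.int(n, replace = TRUE)
        Lb <- L[idx]; Sb <- S[idx]; Ib <- I[idx]
        if (max(Lb) > min(Lb) && max(Sb) > min(Sb) && max(Ib) > min(Ib)) break
        redraws <- redraws + 1L
        if (try == 100) abort("Could not draw a non-degenerate replicate.")
      }
      x <- discretize_quantile(Lb, n_bins)
      z <- discretize_quantile(Sb, n_bins)
      y <- discretize_quantile(Ib, n_bins)
      mi_b[b] <- mutual_information(x, z, correction = correction)
      cmi_b[b] <- conditional_mutual_information(x, z, y,
                                                 correction = correction)
      if (mi_b[b] > log(n_bins) + 1e-9) {
        abort("MI exceeded its ln(K) bound; internal error.")
      }
    }
  })
  if (redraws > 0) {
    message(sprintf("bootstrap_stability: redrew %d degenerate replicate(s).",
                    redraws))
  }
  out <- tibble(s_pair = mean(mi_b > theta), s_triplet = mean(cmi_b > theta),
                delta_s = mean(cmi_b > theta) - mean(mi_b > theta),
                B = B, theta = theta, n_bins = n_bins, seed = seed)
  structure(out, class = c("stability_result", class(out)),
            mi = mi_b, cmi = cmi_b)
}

#' Stability analysis for a table of triplets
#'
#' Applies [bootstrap_stability()] to each (lncRNA, immune, SSG) triplet on
#' the tumour samples of a cohort.
#'
#' @param cohort An [expression_cohort()].
#' @param triplets Tibble with columns `lncRNA`, `immune`, `ssg` (or an
#'   [assemble_triplets()] table, whose immune partners are expanded).
#' @param ... Passed to [bootstrap_stability()]; per-triplet seeds are
#'   offset from `seed`.
#' @param seed Base seed.
#' @return Tibble with one row per triplet: ids plus `s_pair`, `s_triplet`,
#'   `delta_s`.
#' @export
stability_analysis <- function(cohort, triplets, ..., seed = 1) {
  if (!"immune" %in% names(triplets) && "immune_genes" %in% names(triplets)) {
    triplets <- triplets |>
      select("lncRNA", "ssg", "immune_genes") |>
      tidyr::unnest(cols = "immune_genes") |>
      rename(immune = "immune_genes")
  }
  cond <- cohort$samples$condition
  use <- if (any(!is.na(cond) & cond == "tumor")) {
    which(!is.na(cond) & cond == "tumor")
  } else {
    seq_along(cond)
  }
  vals <- cohort$values[, use, drop = FALSE]
  rows <- pmap(list(triplets$lncRNA, triplets$immune, triplets$ssg,
                    seq_len(nrow(triplets))),
               function(ln, im, sg, i) {
    st <- bootstrap_stability(vals[ln, ], vals[sg, ], vals[im, ], ...,
                              seed = seed + i)
    tibble(lncRNA = ln, immune = im, ssg = sg,
           s_pair = st$s_pair, s_triplet = st$s_triplet,
           delta_s = st$delta_s)
  })
  bind_rows(rows)
}
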