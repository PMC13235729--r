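#' Specify a planted regulatory triplet
#'
#' Describes the linear-Gaussian structural equations used to plant one
#' lncRNA/SSG/immune-gene triplet in a synthetic cohort, under one of the
#' four candidate causal patterns:
#'
#' * `IR` (independent regulation, fork): `S = a L + e`, `I = b L + e'`
#' * `CR` (cooperative regulation, collider): `I` exogenous,
#'   `S = a L + b I + e`
#' * `LIS` (chain lncRNA -> immune -> SSG): `I = a L + e`, `S = b I + e'`
#' * `LSI` (chain lncRNA -> SSG -> immune): `S = a L + e`, `I = b S + e'`
#'
#' The lncRNA is always exogenous: `L = N(0, 1) + c * purity`, and in `CR`
#' the exogenous immune gene receives the same additive purity confounding.
#' All disturbances are i.i.d. `N(0, noise_sd^2)`.
#'
#' @param pattern One of `"IR"`, `"CR"`, `"LIS"`, `"LSI"`.
#' @param a,b Structural coefficients (first and second edge).
#' @param noise_sd Positive disturbance standard deviation.
#' @param purity_effect Coefficient `c` of the shared purity confounder.
#' @return A `triplet_spec` list.
#' @export
triplet_spec <- function(pattern, a = 0.8, b = 0.8, noise_sd = 1,
                         purity_effect = 0) {
  if (!pattern %in% PATTERNS) {
    abort(paste0("Unknown pattern '", pattern, "'; expected one of ",
                 toString(PATTERNS), "."))
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) abort("`noise_sd` must be > 0.")
  structure(list(pattern = pattern, a = a, b = b, noise_sd = noise_sd,
                 purity_effect = purity_effect),
            class = "triplet_spec")
}

#' Generate one planted triplet
#'
#' Draws the three expression vectors (L = lncRNA, S = SSG, I = immune gene)
#' of a [triplet_spec()] for `n` samples, given a purity vector. With
#' `noise_sd -> 0`, `a = b = 1` and no purity effect the pattern identities
#' become exact (e.g. `L = S = I` for `LSI`).
#'
#' @param spec A [triplet_spec()].
#' @param n Number of samples (>= 2).
#' @param purity Numeric purity vector of length `n`.
#' @param seed Integer seed; the draw is bit-identical for a fixed seed.
#' @return A list with numeric vectors `L`, `S`, `I`.
#' @export
generate_triplet <- function(spec, n, purity, seed = 1) {
  stopifnot(inherits(spec, "triplet_spec"), n >= 2, length(purity) == n)
  withr::with_seed(seed, {
    cfd <- spec$purity_effect * purity
    L <- rnorm(n) + cfd
    eps <- function() rnorm(n, sd = spec$noise_sd)
    switch(spec$pattern,
      IR = {
        S <- spec$a * L + eps()
        I <- spec$b * L + eps()
      },
      CR = {
        I <- rnorm(n) + cfd
        S <- spec$a * L + spec$b * I + eps()
      },
      LIS = {
        I <- spec$a * L + eps()
        S <- spec$b * I + eps()
      },
      LSI = {
        S <- spec$a * L + eps()
        I <- spec$b * S + eps()
      }
    )
    list(L = L, S = S, I = I)
  })
}

#' Configure a synthetic cohort
#'
#' @param n_samples Number of tumour samples (>= 10).
#' @param triplet_specs List of [triplet_spec()] objects to plant.
#' @param n_null_genes Number of i.i.d. Gaussian background genes, classed
#'   round-robin over lncRNA/immune/SSG.
#' @param seed Master seed; all sub-draws (purity, each triplet, null genes,
#'   survival, normal block) use fixed offsets from it, so adding triplets
#'   does not perturb earlier ones.
#' @param survival_baseline Baseline exponential hazard rate (> 0).
#' @param survival_effect Log-hazard increase per unit of the planted triplet
#'   score (the standardised mean expression of all planted genes).
#' @param censor_horizon Upper end of the uniform censoring window; `Inf`
#'   disables censoring.
#' @param n_normal Size of an optional matched normal block whose per-gene
#'   means are shifted down by `normal_shift` log2 units (for DE testing).
#' @param normal_shift Log2 shift applied to every gene in the normal block.
#' @param base_mean_range Range of the per-gene baseline means added so
#'   values sit on a log-expression-like scale.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_samples, triplet_specs = list(),
                                    n_null_genes = 0, seed = 1,
                                    survival_baseline = 0.1,
                                    survival_effect = 0,
                                    censor_horizon = Inf,
                                    n_normal = 0, normal_shift = 1.5,
                                    base_mean_range = c(2, 6)) {
  if (n_samples < 10) abort("`n_samples` must be >= 10.")
  if (survival_baseline <= 0) abort("`survival_baseline` must be > 0.")
  ok <- vapply(triplet_specs, inherits, logical(1), "triplet_spec")
  if (length(triplet_specs) > 0 && !all(ok)) {
    abort("`triplet_specs` must be a list of triplet_spec objects.")
  }
  structure(list(n_samples = n_samples, triplet_specs = triplet_specs,
                 n_null_genes = n_null_genes, seed = seed,
                 survival_baseline = survival_baseline,
                 survival_effect = survival_effect,
                 censor_horizon = censor_horizon,
                 n_normal = n_normal, normal_shift = normal_shift,
                 base_mean_range = base_mean_range),
            class = "synthetic_cohort_config")
}

#' Generate a synthetic expression cohort with planted triplets
#'
#' Builds a tumour cohort of `n_samples` samples: purity drawn Beta(5, 2),
#' one gene trio per [triplet_spec()] (classed lncRNA/SSG/immune), and
#' `n_null_genes` independent `N(0, 1)` background genes classed round-robin
#' over lncRNA/immune/SSG. Per-gene baseline means (uniform over
#' `base_mean_range`) shift values onto a log-expression-like scale without
#' touching any correlation structure. Survival times are exponential with
#' log-hazard `survival_effect` per unit of the planted triplet score, under
#' independent uniform censoring. When `n_normal > 0`, a matched normal
#' block is appended whose genes are i.i.d. around the tumour baseline minus
#' `normal_shift` (purity left missing for normals).
#'
#' @param config A [synthetic_cohort_config()].
#' @return A list with `cohort` (an [expression_cohort()]) and `provenance`,
#'   a tibble mapping each planted gene to its triplet, role and spec.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  n <- config$n_samples
  seed <- config$seed
  tumor_ids <- sprintf("T%03d", seq_len(n))

  purity <- withr::with_seed(seed + 20000L, rbeta(n, 5, 2))

  specs <- config$triplet_specs
  k <- length(specs)
  rows <- list()
  prov <- list()
  gene_class <- character()
  for (t in seq_len(k)) {
    sp <- specs[[t]]
    trio <- generate_triplet(sp, n, purity, seed = seed + t)
    ids <- c(L = sprintf("lnc_t%d", t), S = sprintf("ssg_t%d", t),
             I = sprintf("imm_t%d", t))
    rows[[ids[["L"]]]] <- trio$L
    rows[[ids[["S"]]]] <- trio$S
    rows[[ids[["I"]]]] <- trio$I
    gene_class[ids] <- c("lncRNA", "SSG", "immune")
    prov[[t]] <- tibble(
      triplet = t, pattern = sp$pattern,
      lncRNA = ids[["L"]], ssg = ids[["S"]], immune = ids[["I"]],
      a = sp$a, b = sp$b, noise_sd = sp$noise_sd,
      purity_effect = sp$purity_effect)
  }

  m0 <- config$n_null_genes
  if (m0 > 0) {
    null_mat <- withr::with_seed(seed + 10000L,
                                 matrix(rnorm(m0 * n), nrow = m0))
    null_ids <- sprintf("null_%03d", seq_len(m0))
    null_cls <- rep(c("lncRNA", "immune", "SSG"), length.out = m0)
    for (g in seq_len(m0)) rows[[null_ids[g]]] <- null_mat[g, ]
    gene_class[null_ids] <- null_cls
  }
  if (length(rows) == 0) abort("Cohort would contain no genes.")

  values <- do.call(rbind, rows)
  colnames(values) <- tumor_ids
  base_mu <- withr::with_seed(
    seed + 40000L,
    runif(nrow(values), config$base_mean_range[1], config$base_mean_range[2]))
  values <- values + base_mu

  # planted triplet score drives survival
  planted <- unlist(lapply(prov, function(p) c(p$lncRNA, p$ssg, p$immune)))
  score <- if (length(planted) > 0) {
    as.numeric(scale(colMeans(values[planted, , drop = FALSE])))
  } else {
    rep(0, n)
  }
  surv <- generate_survival(score, baseline = config$survival_baseline,
                            effect = config$survival_effect,
                            seed = seed + 30000L,
                            censor_horizon = config$censor_horizon)

  condition <- setNames(rep("tumor", n), tumor_ids)
  purity_named <- setNames(purity, tumor_ids)
  surv_df <- data.frame(sample = tumor_ids, time = surv$time,
                        event = surv$event)

  if (config$n_normal > 0) {
    nn <- config$n_normal
    normal_ids <- sprintf("N%03d", seq_len(nn))
    normal_mat <- withr::with_seed(
      seed + 50000L,
      matrix(rnorm(nrow(values) * nn), nrow = nrow(values)))
    normal_mat <- normal_mat + (base_mu - config$normal_shift)
    dimnames(normal_mat) <- list(rownames(values), normal_ids)
    values <- cbind(values, normal_mat)
    condition <- c(condition, setNames(rep("normal", nn), normal_ids))
  }

  cohort <- expression_cohort(values, gene_class = gene_class,
                              condition = condition, purity = purity_named,
                              survival = surv_df)
  provenance <- if (k > 0) bind_rows(prov) else
    tibble(triplet = integer(), pattern = character(), lncRNA = character(),
           ssg = character(), immune = character(), a = numeric(),
           b = numeric(), noise_sd = numeric(), purity_effect = numeric())
  list(cohort = cohort, provenance = provenance)
}

#' Generate exponential survival driven by a linear score
#'
#' `time ~ Exponential(rate = baseline * exp(effect * score))` with
#' independent `Uniform(0, censor_horizon)` censoring; `event = 1` when the
#' death time precedes the censoring time.
#'
#' @param scores Numeric per-sample score vector.
#' @param baseline Baseline hazard rate (> 0).
#' @param effect Log-hazard per unit score.
#' @param seed Integer seed.
#' @param censor_horizon Censoring window upper end; `Inf` disables
#'   censoring.
#' @return Tibble with columns `time`, `event`.
#' @export
generate_survival <- function(scores, baseline, effect, seed = 1,
                              censor_horizon = Inf) {
  if (baseline <= 0) abort("`baseline` must be > 0.")
  n <- length(scores)
  withr::with_seed(seed, {
    rate <- baseline * exp(effect * scores)
    t_event <- rexp(n, rate = rate)
    if (is.finite(censor_horizon)) {
      t_cens <- runif(n, 0, censor_horizon)
      tibble(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
    } else {
      tibble(time = t_event, event = 1L)
    }
  })
}

#' Generate a pure-null cohort
#'
#' All genes are mutually independent standard normals (plus per-gene
#' baseline means); used for permutation-null and FDR calibration checks.
#' Gene classes rotate over lncRNA/immune/SSG. An optional `n_normal` block
#' labels the last samples `"normal"` (the values are exchangeable, so any
#' labelling is a valid null).
#'
#' @param n_genes,n_samples Dimensions.
#' @param seed Integer seed.
#' @param n_normal How many trailing samples to label `"normal"`.
#' @return An [expression_cohort()] (purity drawn Beta(5, 2), unrelated to
#'   expression).
#' @export
generate_null_cohort <- function(n_genes, n_samples, seed = 1,
                                 n_normal = 0) {
  stopifnot(n_genes >= 1, n_samples >= 2, n_normal < n_samples)
  values <- withr::with_seed(
    seed, matrix(rnorm(n_genes * n_samples), nrow = n_genes))
  ids <- sprintf("g%04d", seq_len(n_genes))
  smp <- sprintf("s%04d", seq_len(n_samples))
  dimnames(values) <- list(ids, smp)
  purity <- withr::with_seed(seed + 20000L, rbeta(n_samples, 5, 2))
  condition <- rep("tumor", n_samples)
  if (n_normal > 0) {
    condition[(n_samples - n_normal + 1):n_samples] <- "normal"
  }
  expression_cohort(
    values,
    gene_class = setNames(rep(c("lncRNA", "immune", "SSG"),
                              length.out = n_genes), ids),
    condition = setNames(condition, smp),
    purity = setNames(purity, smp))
}

#' Build immune-pathway gene sets for a synthetic cohort
#'
#' Assembles a [gene_set_collection()] over the cohort's immune-classed
#' genes: the first set contains all `planted_immune` genes (padded with
#' null immune genes), the remaining sets are random immune subsets. This
#' stands in for curated immune-pathway GMT collections when exercising the
#' pipeline on synthetic data.
#'
#' @param cohort An [expression_cohort()].
#' @param planted_immune Immune genes that must appear in the first set.
#' @param n_sets Number of sets.
#' @param set_size Target set size.
#' @param seed Integer seed.
#' @return A [gene_set_collection()].
#' @export
synth_gene_sets <- function(cohort, planted_immune = character(),
                            n_sets = 3, set_size = 6, seed = 1) {
  immune <- cohort$genes$gene_id[cohort$genes$class == "immune"]
  if (length(immune) == 0) abort("Cohort has no immune-classed genes.")
  missing <- setdiff(planted_immune, immune)
  if (length(missing) > 0) {
    abort(paste0("Not immune genes in cohort: ", toString(missing)))
  }
  withr::with_seed(seed, {
    sets <- list()
    pool <- setdiff(immune, planted_immune)
    pad <- sample(pool, min(max(set_size - length(planted_immune), 0),
                            length(pool)))
    sets[["immune_set_1"]] <- c(planted_immune, pad)
    if (n_sets > 1) {
      for (s in 2:n_sets) {
        sets[[sprintf("immune_set_%d", s)]] <-
          sample(immune, min(set_size, length(immune)))
      }
    }
    gene_set_collection(sets)
  })
}
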