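# stemlnc

Infer **core regulatory triplets** — one lncRNA, one immune gene, one
stemness signature gene (SSG) — from tumour expression cohorts, decide
which causal pattern best explains each triplet, quantify its robustness,
and score its clinical relevance.

Cancer stem-cell programs and immune evasion are linked, and lncRNAs sit
upstream of both: a lncRNA that co-regulates an SSG and an immune gene is a
candidate lever on tumour stemness *and* the immune microenvironment.
`stemlnc` is for computational biologists who have a genes × samples
expression matrix (log2(TPM + 1) scale, batch-corrected upstream), gene
class annotations, optional tumour purity and survival metadata, and want a
reproducible, testable pipeline from that matrix to a ranked triplet table.

## The method in brief

1. **Screen.** Welch-t differential expression (|log2FC| > 1, BH-FDR
   < 0.05); optional SSG nomination by random walk with restart on a PPI
   network, `p(t+1) = (1−r) A p(t) + r p(0)`, r = 0.85, keeping the top 5%;
   co-expression network (|r| ≥ 0.3, FDR < 0.05) and personalised PageRank
   seeded at SSGs to shortlist the top 200 lncRNAs and immune genes.
2. **Score pairs.** For each lncRNA–SSG pair, a weighted
   partial-correlation score over immune genes i,

   `WPC = Σ_i β_i ( −log10(P_i⁽¹⁾)·sign(cor_i⁽¹⁾) − log10(P_i⁽²⁾)·sign(cor_i⁽²⁾) )`,

   where the partial correlations control for tumour purity,
   `pcc = (R_xy − R_xp R_yp)/(√(1−R_xp²)·√(1−R_yp²))`, and β_i comes from a
   GSEA running sum over immune pathways. Significance: shuffle the
   lncRNA's sample labels, `p = N/n_perm` (two-sided exceedance), BH across
   pairs, keep FDR < 0.05.
3. **Select patterns.** Fit the four linear-Gaussian factorisations — IR
   fork `P(L)P(S|L)P(I|L)`, CR collider `P(L)P(I)P(S|L,I)`, chains LIS
   `P(L)P(I|L)P(S|I)` and LSI `P(L)P(S|L)P(I|S)` — and pick the minimum
   `BIC = k ln n − 2 ln L̂`, reporting weights `ω_i ∝ exp(−Δ_i/2)`.
4. **Stability.** Bootstrap the samples, discretise into 5 equiprobable
   bins, and report `S_pair = mean[I_b(X;Z) > θ]`,
   `S_triplet = mean[I_b(X;Z|Y) > θ]` and `ΔS` (θ = 0.2, B = 200).
5. **Clinical.** Cox triplet score
   `coef_lnc·exp_lnc + coef_imm·exp_imm + coef_ssg·exp_ssg`, maximally
   selected log-rank stratification, dual Cox/log-rank prognostic screen,
   breadth classification (common > 10 cancer types, specific ≤ 2) and
   hypergeometric overlap tests.

A synthetic-cohort generator plants triplets under each pattern with a
shared purity confounder, null background genes and exponential survival,
so the whole pipeline is testable without any downloads. See the methods
vignette (`vignettes/stemlnc-methods.Rmd`) for models, assumptions,
estimator caveats and design rationale.

## Worked example

```r
library(stemlnc)

specs <- list(triplet_spec("IR"), triplet_spec("LIS"), triplet_spec("LSI"))
cfg <- synthetic_cohort_config(300, specs, n_null_genes = 30, seed = 42,
                               n_normal = 100, normal_shift = 1.5,
                               survival_baseline = 0.2, survival_effect = 1,
                               censor_horizon = 25)
sim <- generate_cohort(cfg)

de  <- differential_expression(sim$cohort)
net <- build_coexpression_network(sim$cohort, de = de)
pri <- pagerank_prioritize(net, intersect(sim$provenance$ssg, net$nodes),
                           gene_classes(sim$cohort))
gmt <- synth_gene_sets(sim$cohort, planted_immune = sim$provenance$immune,
                       seed = 43)
trip <- assemble_triplets(sim$cohort,
                          lncRNAs = pri$gene_id[pri$class == "lncRNA"],
                          ssgs = de$gene_id[de$passes & de$class == "SSG"],
                          immune_pathways = gmt,
                          n_perm = 200, n_gsea_perm = 200, seed = 44)
head(dplyr::select(trip, lncRNA, ssg, n_immune, wpc, perm_p, fdr), 5)
#>   lncRNA ssg    n_immune   wpc perm_p   fdr
#> 1 lnc_t1 ssg_t3       11  62.5      0     0
#> 2 lnc_t2 ssg_t2       11  62.3      0     0
#> 3 lnc_t1 ssg_t2       11  62.0      0     0
#> 4 lnc_t2 ssg_t3       11  60.2      0     0
#> 5 lnc_t3 ssg_t3       11  56.4      0     0
```

All three planted (lncRNA, SSG) pairs are in the retained table (a `perm_p`
of 0 means "below 1/200"; pairs sharing a planted lncRNA also score highly
because the WPC measures lncRNA–immune co-regulation). Pattern selection on
the planted triplets recovers every generative structure:

```r
pats <- infer_patterns(sim$cohort, sim$provenance)
dplyr::select(pats, lncRNA, immune, ssg, selected)
#>   lncRNA immune    ssg selected
#> 1 lnc_t1 imm_t1 ssg_t1       IR
#> 2 lnc_t2 imm_t2 ssg_t2      LIS
#> 3 lnc_t3 imm_t3 ssg_t3      LSI
```

Stability and survival utilities chain on the same objects:

```r
stability_analysis(sim$cohort, sim$provenance, B = 50, seed = 45)
#>   lncRNA imm_t* ssg_t*  s_pair s_triplet delta_s   (one row per triplet)

model <- fit_triplet_score(sim$cohort,
                           unlist(sim$provenance[2, c("lncRNA", "immune",
                                                      "ssg")]))
smp <- sample_info(sim$cohort); ok <- !is.na(smp$time)
optimal_cutoff_stratify(model$scores$score[ok], smp$time[ok], smp$event[ok])
#> <cutoff_stratification> cutoff = 1.565 (low n=192, high n=108),
#>   chisq = 38.085, log-rank p = 6.77e-10
```

The planted survival effect (log-hazard 1 per unit triplet score) is picked
up as a strongly significant stratification. Fitted objects support
`tidy()`, `glance()` and `autoplot()`; `plot_wpc_null()`,
`plot_stability_summary()` and `plot_km_strata()` cover the remaining
result types. A thin command-line wrapper with `simulate` / `screen` /
`triplets` / `patterns` / `stability` / `score` subcommands lives at
`inst/cli/stemlnc.R`.

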