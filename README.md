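# ahrfsig

Cross-cohort discovery of whole-blood gene-expression signatures of severe
pediatric acute hypoxemic respiratory failure (AHRF), for computational
biologists who need the full workflow — cohort simulation, preprocessing,
stability selection, signature evaluation, enrichment, and network hubs —
as reproducible, tested R functions.

## The method

Children with AHRF are split at a P<sub>a</sub>O<sub>2</sub>/F<sub>i</sub>O<sub>2</sub>
ratio of 200: below 200 is the *case* (moderate/severe) class, 200–300 the
*control* (mild) class. A per-gene Welch + Benjamini–Hochberg screen finds
no genes shared between independent cohorts, so the package instead ranks
genes by **bootstrap stability selection**: over *B* = 100 stratified
bootstrap draws, an L1-penalized logistic regression
(λ = 1/(n·C), C = 1) is fit on each draw, and gene *g* receives the
stability score

  Π̂(g) = #{b : |β̂<sub>g</sub><sup>(b)</sup>| > ε} / B,

its selection frequency across draws (ε = 10⁻⁸; genes with Π̂ ≥ 0.6 are
flagged). Each cohort's genes are ranked by Π̂; the **top-1,500 lists of the
two cohorts are intersected**, the common genes are ordered by rank sum,
and nested signatures are grown incrementally. Every signature size is
scored by **leave-one-out cross-validation** with an L2 logistic classifier:
AUROC (rank-sum concordance, ties ½) and AUPRC (step-wise average
precision) on the pooled out-of-fold scores, with stratified percentile
bootstrap 95% CIs. The optimal size maximizes AUROC (ties → smallest).
Downstream, the signature is tested for over-representation against GMT
gene sets (one-sided hypergeometric, BH FDR) and hub genes (degree ≥ 10)
are reported from a SIF protein-interaction network.

A synthetic twin-cohort generator with planted, partially shared
informative genes provides ground truth for every stage, so the whole
pipeline runs and is tested without any external download.

## Worked example

```r
library(ahrfsig)

cfg <- validate_config(list(
  seed = 7, shared_informative = 20,
  cohorts = list(
    a = list(n_cases = 40, n_controls = 20, n_genes = 600, n_informative = 30),
    b = list(n_cases = 45, n_controls = 25, n_genes = 600, n_informative = 30)),
  stability = list(n_boot = 25),
  signature = list(top_k = 60, step = 10, ci_resamples = 200)))
res <- run_pipeline(cfg, "ahrf_run")

res$opt_size
#> [1] 10
nrow(res$common)
#> [1] 15
head(res$enrichment, 2)
#> # A tibble: 2 × 6
#>   set            found set_size entities_ratio        p      fdr
#>   <chr>          <int>    <int>          <dbl>    <dbl>    <dbl>
#> 1 PLANTED_SET       10       20         0.0333 1.20e-16 2.39e-15
#> 2 RANDOM_SET_007     2       50         0.0833 1.99e- 1 1   e+ 0
res$hubs
#> [1] "G00024" "G00081" "G00104"
```

Two synthetic cohorts are generated, preprocessed (quantile normalization →
probe collapsing → per-batch standardization), ranked by stability
selection, and intersected at the top 60; the 15 common genes are evaluated
in 10-gene steps and the 10-gene prefix already maximizes LOOCV AUROC at
this small scale. The planted gene set dominates the enrichment table
(hypergeometric p ≈ 10⁻¹⁶) and the three planted network hubs are
recovered. `ahrf_run/` contains every stage output (TSV/CSV/GMT/SIF/JSON)
plus `manifest.json`; re-running with the same config and seed reproduces
all outputs byte-identically except `timings.json`.

The same pipeline runs from a shell:

```sh
Rscript inst/scripts/run-pipeline.R --config run.yaml --out ahrf_run --seed 7
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `cohort_spec`, `generate_cohort`, `generate_paired_cohorts`, `generate_gene_sets`, `generate_network`, `write_truth_json` |
| Preprocessing | `quantile_normalize`, `collapse_probes`, `batch_correct`, `differential_expression` |
| Stability selection | `stability_config`, `bootstrap_indices`, `fit_sparse_logistic`, `stability_select`, `rank_genes` |
| Signature | `common_genes`, `incremental_sets`, `auroc`, `auprc`, `loocv_evaluate`, `bootstrap_ci`, `evaluate_curve`, `select_optimal` |
| Enrichment | `read_gmt`, `write_gmt`, `ora`, `pathway_gene_counts`, `set_overlap_edges` |
| Network | `read_sif`, `write_sif`, `find_hubs`, `node_table` |
| Pipeline | `validate_config`, `write_config`, `run_pipeline` |

The methods vignette (`vignettes/signature-discovery.Rmd`) documents the
generative model, the statistical conventions, and the design decisions in
detail.
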