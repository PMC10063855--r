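---
title: "Cross-cohort signature discovery with bootstrap stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort signature discovery with bootstrap stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahrfsig)
```

## The problem

Children admitted to intensive care with acute hypoxemic respiratory failure
(AHRF) span a wide severity range, conventionally split at a
P~a~O~2~/F~i~O~2~ ratio of 200 (below 200 = moderate/severe, the "case"
class here; 200–300 = mild, the "control" class). Whole-blood expression
arrays from two independent pediatric cohorts — an ARDS-specific cohort with
26 mild and 70 moderate/severe children, and a sepsis-triggered AHRF cohort
with 65 mild and 96 moderate/severe — offer a route to a transcriptomic
severity signature, but a conventional per-gene differential-expression
screen with Benjamini–Hochberg correction finds no genes shared between the
cohorts. `ahrfsig` implements the alternative: rank genes within each cohort
by *stability selection*, intersect the two top-1,500 ranked lists, grow the
common-gene signature incrementally, and pick the size that maximizes
leave-one-out cross-validated discrimination.

Because the original cohorts live in a public repository and the package
must be testable without downloads, every stage is exercised end-to-end on a
synthetic twin-cohort generator with known ground truth. The generator is
first-class, tested code, not a throwaway fixture.

## The synthetic twin-cohort generator

`cohort_spec()` / `generate_cohort()` simulate a microarray-like cohort on
the log2 scale:

* each gene has a baseline drawn once from Normal(7, 1.5) log2 units —
  typical log-intensities;
* per sample, the gene-level signal is Normal(baseline + shift, `noise_sd`),
  where the shift is `±effect_size` in cases for the planted informative
  genes (sign drawn per gene with equal probability, recorded in the truth)
  and zero otherwise;
* each probe of a gene observes the gene signal plus independent
  Normal(0, `0.25 * noise_sd`) probe noise; by default 70% of genes carry
  one probe, 25% two, 5% three;
* each batch adds one offset drawn from Normal(0, `batch_shift_sd`), shared
  by all genes in the batch; samples are assigned to batches round-robin
  within class, so batches stay class-balanced.

`generate_paired_cohorts()` creates two cohorts over the same gene universe
with exactly `shared_informative` planted genes in common — the quantity the
cross-cohort intersection is supposed to recover.

Defaults: 5,000 genes, 50 informative per cohort, 30 shared, 2 batches with
`batch_shift_sd = 0.5`, `noise_sd = 1`, `effect_size = 0.75`. The effect
size deserves a comment, since no published estimate exists for these
cohorts. 0.75 log2 units at unit noise gives a single planted gene an AUROC
of about 0.70 — a modest marker — while a panel of a few dozen such genes
discriminates strongly. Discrimination therefore *rises through* the
evaluated signature sizes instead of saturating at the first size, which is
the qualitative behavior the optimum-size selection exists to detect; the
emulated cohorts' published discrimination is similarly modest. A 2-SD
effect, by contrast, makes ten genes already near-perfect, and the
smallest-size tie rule would then (correctly, but uninformatively) stop the
signature at the first evaluated size.

What the generator does **not** emulate: probe-sequence (GC) artifacts,
gene–gene correlation blocks, latent (unrecorded) batch structure,
platform-specific annotation, and heavy-tailed noise. Tests passing on this
generator therefore demonstrate the pipeline's *mechanics* — ranking,
intersection, evaluation, calibration under a true null — not performance
on real arrays, where correlated genes and latent confounding make
everything harder.

## Preprocessing

The probe-level preprocessing chain is deliberately simple and explicit:

1. **Quantile normalization** (`quantile_normalize()`, via
   `limma::normalizeQuantiles`): every sample column is forced to the
   row-wise mean of the sorted columns; ties receive the mean of the
   quantile values they span. Input is assumed log2; pass
   `log2_transform = TRUE` for linear-scale matrices.
2. **Probe collapsing** (`collapse_probes()`): probes of one gene are
   averaged on the log2 scale; unannotated probes are dropped with a
   message; a probe mapped to two genes is an error, not a guess.
3. **Batch correction** (`batch_correct()`): within each known batch, every
   gene is centered and scaled to unit variance. This removes the additive
   offsets the generator plants *exactly*, at the cost of also removing
   scale information; genes constant within a batch are centered only and
   flagged. Latent-confounder estimation is intentionally out of scope —
   batch labels are explicit inputs here.
4. **DE screen** (`differential_expression()`): per-gene Welch t-test
   (unequal variances — the emulated cohorts have unequal group sizes),
   two-sided p, BH q-values. Genes with zero variance in both classes get
   p = 1. The screen documents the motivation for the machine-learning
   route; it is not itself used for selection.

## Stability selection

`stability_select()` runs `n_boot = 100` stratified bootstrap iterations.
Per iteration:

* `bootstrap_indices()` draws `n` samples with replacement, preserving the
  case/control mix (stratification keeps every draw two-class and the
  prevalence fixed); the draw is a pure function of `(seed, iteration)`;
* features are standardized *on the draw only* (no leak from out-of-draw
  samples);
* an L1-penalized logistic regression (glmnet) is fit at the single penalty
  `lambda = 1 / (n * penalty_strength)` — the same objective scaling as the
  inverse-regularization `C` of scikit-learn-style solvers, with
  `penalty_strength = 1` by default; the intercept is unpenalized;
* genes with |coefficient| > `coef_epsilon` (1e-8) count as selected.

A gene's **stability score** is its selection frequency over all `n_boot`
iterations; the denominator stays `n_boot` even if iterations are skipped
for non-convergence (a run fails if more than 10% skip). Genes are ranked
by descending score, ties by descending mean absolute coefficient, then
lexicographically — fully deterministic. Samples are put in canonical
(sorted-ID) order before seeding, so results do not depend on input column
order. Class encoding is fixed: case = 1, control = 0.

Two behaviors of single-penalty lasso stability selection are worth knowing
before reading scores:

* **Null scores are small but not zero.** A finite null cohort (96 samples,
  5,000 genes) contains a few noise genes with genuine sample-level class
  association (the maximum spurious |t| is around 4.5), and bootstrap draws
  share about 63% of their samples, so such a gene is re-selected
  consistently at any penalty. In practice roughly 0–3 genes per 5,000
  (≤ 0.1%) reach the 0.6 threshold on a true null, with scores below 0.8.
  The threshold is a ranking device, not an error-controlled test.
* **Competition among equally strong markers dilutes scores.** When many
  planted genes each separate the classes well, the draw is (nearly)
  linearly separable and the lasso needs only a subset of them; membership
  rotates across draws, so individual scores fall well below 1 even though
  every such gene ranks far above the noise. Near-unit scores are expected
  only for markers without strong substitutes. Rank lists are therefore the
  robust output; absolute scores are secondary.

## Signature construction and evaluation

`common_genes()` intersects the two cohorts' top-`top_k` (default 1,500)
ranked lists. The joint ordering of the intersection — ascending rank sum,
ties by minimum single-cohort rank, then gene ID — is a package convention:
some deterministic joint order is required before incremental growth, and
rank sum is the symmetric choice. `incremental_sets()` grows nested
prefixes either in steps of 10 genes (default) or at explicit sizes; both
modes exist because a 10-gene step and an irregular evaluated grid such as
12/21/48/69/92/185 are both sensible reporting conventions, and the
explicit grid is what the package's own full-scale runs use.

`loocv_evaluate()` scores each sample with an L2-penalized logistic
regression trained on all other samples (standardized on the training
fold), then computes AUROC and AUPRC once on the pooled out-of-fold scores.
L2 rather than L1 inside evaluation avoids re-running selection per fold;
the penalty (`ridge_penalty`, same `1/(n * c)` scaling) is config-exposed.
With a single gene the fold model falls back to unpenalized logistic
regression, since the elastic-net solver requires two columns; with one
predictor the out-of-fold score is monotone in the gene either way.
LOOCV involves no randomness and is fully deterministic.

Metric conventions:

* **AUROC** is the rank-sum (Mann–Whitney) concordance probability, ties
  counting ½.
* **AUPRC** is step-wise average precision with no interpolation; tied
  scores enter as a single threshold, so a constant scorer yields exactly
  the prevalence. Interpolated PR areas overestimate and are not
  comparable.
* **Confidence intervals** (`bootstrap_ci()`) are percentile intervals over
  resamples stratified by class — stratification preserves prevalence,
  which AUPRC depends on, and guarantees two-class resamples. The interval
  is widened, never narrowed, to cover the point estimate, so the
  documented `lower ≤ point ≤ upper` invariant holds even in degenerate
  near-perfect cases. Whether analytic or bootstrap intervals were the
  original convention for such curves is unknowable from reported numbers
  alone; percentile bootstrap is the package convention.

`select_optimal()` returns the size maximizing the chosen metric (AUROC by
default), averaged across cohorts when several are evaluated, with ties
going to the smallest size — the parsimony rule.

## Downstream analyses

`ora()` tests each gene set for over-representation of the signature with
the one-sided upper-tail hypergeometric probability
(population = universe, successes = set ∩ universe, draws = hits) and BH
FDR across sets. The universe defaults to all genes on the collapsed
expression matrix — the defensible choice when no curated universe is
given — and is config-overridable. Depletion is deliberately not tested.
Multi-level pathway-network crawling is reduced to flat per-set testing
plus a Jaccard > 0.25 set-overlap edge list for external visualization.

`read_sif()` / `find_hubs()` load a simple undirected interaction graph
(reversed duplicates collapsed, self-loops dropped with a warning,
multi-target lines expanded pairwise) and report nodes with degree ≥ 10,
the conventional protein-interaction hub cutoff. Edge provenance is the
user's responsibility; the package does not query interaction databases.

## The pipeline and reproducibility

`run_pipeline()` orchestrates everything from one validated YAML/list
config (`validate_config()`, JSON schema in
`inst/extdata/run-config-schema.json`) and one global seed. Per-stage seeds
are derived as
`hash(stage name) * 131 + (seed %% 65011) * 48271 (mod 2^31 - 19) + 1`,
one independent stream per stage, all below 2^31. Re-running with the same
config and seed reproduces every output byte-for-byte; wall-clock timings
live in a separate `timings.json` precisely so the rest of the bundle is
comparable. Logs are line-delimited JSON.

A worked example at desk scale:

```{r example, eval = FALSE}
cfg <- list(
  seed = 7, shared_informative = 20,
  cohorts = list(
    a = list(n_cases = 40, n_controls = 20, n_genes = 600, n_informative = 30),
    b = list(n_cases = 45, n_controls = 25, n_genes = 600, n_informative = 30)),
  stability = list(n_boot = 25),
  signature = list(top_k = 60, step = 10, ci_resamples = 200))
res <- run_pipeline(validate_config(cfg), "ahrf_run")
res$opt_size
head(res$enrichment)
```

## Numerical choices and degenerate inputs

* Constant features get unit scale during standardization (coefficient 0
  follows), never NaN.
* Zero-variance genes: p = 1 in the DE screen; centered-only (and flagged)
  in batch correction.
* Missing expression values are a hard load error — silent imputation hides
  format bugs in dense array matrices.
* Non-convergent selector iterations are skipped and counted; > 10% skips
  abort the run.
* Empty top-k intersection produces an explicit empty result with a warning
  at the operation level and a clean abort at the pipeline level.
* Optimum ties resolve to the smallest size; rank ties resolve by
  coefficient then gene ID; common-gene ties by minimum rank then gene ID.

## Problem sizes used by the shipped checks

The package's own full-scale runs (the acceptance script) use the emulated
cohorts' sample sizes (70/26 and 96/65), 5,000 genes, 50 informative with
30 shared, 100 bootstrap iterations, top-1,500 intersection, and the
explicit evaluation grid 12/21/48/69/92/185. The test suite asserts the
same properties at smaller sizes (typically 250–2,000 genes and 15–100
iterations), except the null-calibration checks, which run at the full
5,000 genes because spurious-selection rates depend on the competing-gene
count.

## Known limitations

* Independent genes only; no correlation blocks, so stability scores on
  real arrays (where substitutes abound) will be lower and rank lists
  noisier than on synthetic twins.
* Per-batch standardization assumes batch labels are known and the batch
  effect is additive and gene-constant; latent or gene-specific batch
  structure is out of scope.
* The DE screen's test (Welch) and FDR cutoff are configuration defaults,
  not a claimed replication of any particular published screen.
* Single-penalty stability selection carries no finite-sample
  false-selection guarantee; the 0.6 threshold is a ranking convenience.
* ORA treats gene sets as flat and ignores set overlap in testing.
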