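---
title: "Site-specific prognostic signature discovery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-specific prognostic signature discovery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery in `sitesig`: the models
and their assumptions, the tunable parameters, the synthetic-data generator
that backs the test suite, and the numerical and design choices made where
the methodology left room.

## The problem

Cardia and non-cardia gastric tumours are treated as separate cohorts
throughout: every filter statistic, every feature-selection run and every
prognostic model sees one site's samples only. The pipeline starts from a
features-by-samples matrix of non-negative, FPKM-like expression values
(genes, miRNAs or lncRNAs) and a sample table carrying tissue type
(tumour/normal), anatomic site, overall-survival time and event indicator,
and clinical covariates. All expression enters models on the log2(x+1)
scale; call rate and fold change are computed on the raw scale. The
container tracks its scale explicitly and `log_transform()` refuses to run
twice.

## The candidate filter

A feature is a site-specific candidate when all four hold strictly:

* call rate > 0.70 — fraction of the site's samples (tumour and normal
  jointly) with raw value > 0. The sample set for call rate is a
  documented choice (`filter_features()`), since tumour-only is equally
  defensible.
* |log2 FC| > 1 with FC = mean raw tumour / mean raw normal. Raw-scale
  means match how FPKM tables are conventionally reported; a
  `fc_on_log` switch computes the ratio of geometric-style means instead.
  An infinite FC (zero normal mean, nonzero tumour mean) passes the
  criterion and is flagged in the report.
* Welch t-test p < 0.05 on log2(x+1) values. Welch is the default because
  tumour/normal group sizes are typically very unbalanced (e.g. 150 vs 32);
  `welch = FALSE` gives the pooled-variance test.
* univariate Cox p < 0.05 (Wald) for the log2 expression among the site's
  tumours.

No multiple-testing correction is applied at this stage; the filter is a
screen, and the downstream cross-validated selection carries the burden of
controlling optimism.

## Genetic-algorithm wrapper selection

`ga_evolve()` searches binary inclusion masks over the candidates with a
pluggable fitness in [0, 1]. The published description of this class of
method fixes only selection, crossover, mutation and the generation count,
so the operator details are package choices, all exposed in `ga_params()`:

| parameter | default | rationale |
|---|---|---|
| generations | 200 | headline setting; 30–50 suffice for pools of ≤ 100 candidates and are used in tests |
| population | 100 | standard wrapper-selection default |
| selection | tournament, size 2 | weak, diversity-preserving pressure |
| crossover | uniform, rate 0.8 | standard for fixed-length binary masks |
| mutation | per bit, max(1/p, 0.01) | one expected flip per chromosome |
| elitism | 1 | makes the best-fitness trace non-decreasing |
| initialisation | each bit set w.p. min(0.5, 10/p) | small initial subsets, matching the small signatures the method targets |

A chromosome mutated to all-zero has one uniformly random bit restored; a
fitness of NaN is recorded as 0 and counted. Every unique mask ever
evaluated is archived with its fitness. The "top 50 subsets" consumed by
the frequency ranking are drawn from that whole-run archive rather than
the final generation (`pool = "final"` restores the alternative): the
archive view is the natural reading of extracting the best sets *after*
the run, and it is strictly richer. Feature ties in the frequency ranking
break by mean fitness of the containing subsets, then candidate index.

Both fitness functions share stratified 3-fold cross-validation
(`make_folds()`), with folds fixed *before* any mask is seen, so fitness
values are comparable across masks. The forward-selection step re-evaluates
prefixes of the frequency ranking under a fresh fold seed and picks the
first maximum of the AUC-versus-k curve.

* **SVM fitness** — linear kernel, C = 1, balanced class weights, features
  standardized with training-fold statistics; held-out decision values are
  scored by rank AUC. The kernel and cost are package choices (no kernel is
  prescribed by the methodology); linear is the conventional choice when
  p ≥ n and keeps decision values interpretable. The SVM convergence
  tolerance is 0.01 (libsvm default 0.001); at these sample sizes the
  held-out decision values are indistinguishable while training is ~25%
  faster.
* **Cox fitness** — a multivariable Cox model per training fold; held-out
  risk scores are scored by the time-dependent AUC at 60 months
  ("5-year survival", months being the time unit throughout). Non-convergent
  fits score 0. The fold-level ROC uses the Kaplan–Meier variant of the
  estimator: held-out folds are small (n/3), where the nearest-neighbour
  span 0.25·n^(−0.20) is unstable; the variant is switchable
  (`roc_method`).

## Risk score and survival models

The signature's risk score is ∑ βᵢXᵢ with βᵢ from one multivariable Cox
fit on the full site cohort (Efron ties) and Xᵢ the log2(x+1) expression.
Multivariable (rather than univariate) coefficients are used because the
score feeds a joint model; collinear signatures trigger a ridge-stabilized
refit (penalty 1e-4) with a warning. Patients are split at the median
score — strictly-above goes high-risk, ties at the median go low, so group
sizes differ by at most one — and compared by Kaplan–Meier and log-rank.

The clinical ("traditional") model is a p-value stepwise Cox fit: forward
entry at the smallest likelihood-ratio p < 0.05, backward removal at
p > 0.10, iterated to a fixed point. Likelihood-ratio p-values are used
(Wald would be the other defensible reading). The combined model appends
the risk score as a single continuous covariate to the selected clinical
covariates. Binary/ordinal clinical covariates are coded numerically
(0/1 and stage 1–4), which is also how the nomogram maps them.

Models are compared by the time-dependent AUC at 60 months, apparent and
3-fold cross-validated, plus a bootstrap comparison: B resamples of the
cohort, each model's AUC per resample, and a two-sided Wilcoxon rank-sum
test between the two AUC samples. The resampling design is a package
choice; only the test itself is prescribed.

## Time-dependent ROC, concordance, nomogram

`td_roc()` implements the cumulative-case / dynamic-control estimator:
cases have an observed event by the horizon, controls are event-free past
it. The default is the nearest-neighbour bivariate survival estimator with
span 0.25·n^(−0.20) (the reference implementation's documented default);
neighbourhoods are percentile windows of half-width equal to the span, so
the estimate — and its AUC — is invariant under strictly monotone score
transforms. The Kaplan–Meier variant (conditional KM within marker
subgroups, computed for all nested subgroups in one cumulative pass) is
retained as the simplest method; on uncensored data it reduces *exactly*
to the empirical ROC, which the tests assert to 1e-10. AUC is the
trapezoid along the cutoff-parametrized curve.

`c_index()` is Harrell's concordance over comparable pairs (the member
with shorter follow-up experienced the event; tied times are comparable
only when exactly one is an event; tied scores count 0.5).
`bootstrap_cindex()` applies the standard optimism correction: refit on
each of B = 1000 resamples, average the (resample C − original-data C)
gap, subtract it from the apparent C.

`build_nomogram()` assigns covariate j the points
100·|βⱼ|·(x − x_ref,j)/max_k(|β_k|·range_k), with the reference at the
range endpoint of minimum risk, so the most influential covariate spans
0–100 and all points are non-negative. Total points map affinely back to
the linear predictor, and survival is S₀(t)^exp(lp − lp̄) with the Breslow
baseline at covariate means. Because the map is affine the chain
covariates → points → total points → survival reproduces the model's
direct prediction exactly; the tests hold every patient to 1e-10.
Zero-range covariates are excluded with a warning.

Calibration bins patients into equal-size groups (default 3) by predicted
survival and compares the group's mean prediction with its KM estimate at
the horizon, with a bootstrap percentile CI. Decision curves report net
benefit TP/n − (FP/n)·p_t/(1−p_t) with the event probability among
"treated" patients estimated by KM, which handles censoring; treat-all and
treat-none references are included. Calibration and decision curves
default to 36 months — few site-specific patients have follow-up beyond
5 years, so the 3-year horizon is better supported — while the nomogram
headline horizon stays at 60 months.

## The synthetic-data generator

`simulate_site_data()` produces the structure the pipeline assumes,
per site with independent truth:

* **Expression** — i.i.d. log-normal(meanlog = 1, sdlog = 1) on the raw
  scale, mimicking FPKM skew; planted differential features have the
  tumour meanlog shifted by log2FC·log(2) so their population log2 fold
  change equals the configured value (2 by default); every value is
  independently zeroed with probability 0.1 to exercise the call-rate
  criterion.
* **Survival** — exponential event times with hazard
  h₀·exp(∑βⱼzⱼ + clinical terms), zⱼ the centred, unit-scaled log2
  expression of the planted prognostic features (default β = 0.8 each).
  h₀ = 0.005/month puts the median survival of a typical patient near
  2–3 years with a realistic fraction of the cohort evaluable at 60
  months. Censoring is the minimum of an independent exponential time
  (rate 0.015/month) and an administrative cap at 120 months — the
  censoring model is a package choice, as none is prescribed.
* **Clinical covariates** — neoplasm status, residual tumour, radiation
  therapy and stage, with log-hazards (1.0, 1.2, −0.8, 0.45 per stage
  level) taken from the magnitude of the corresponding published
  univariate hazard ratios, so the clinical-only model is non-trivial and
  the added value of an expression signature can be measured against it.

What the generator deliberately does **not** emulate: batch structure,
correlation between features or between modalities, copy-number coupling,
non-proportional hazards. Passing tests therefore demonstrate that the
machinery recovers planted effects under its own assumptions, not that it
would perform identically on TCGA-scale data.

## Problem sizes used in validation

The test suite validates at deliberately modest scales: GA recovery runs
use 100 candidates, 5 planted features, 300 patients, 50 generations and
population 50 (20 replicates per selector); the GA-optimality check uses
12 candidates against brute-force enumeration of all 2^12−1 subsets; null
calibration uses 1000 features for the filter level and 20 GA runs at the
same scale as the recovery runs, with every planted effect (expression and
clinical) set to zero, for the selection-optimism guard; the added-value
comparison uses 200 patients per replicate.
These sizes give stable pass/fail behaviour for the properties being
tested while keeping a full run of the suite inside an ordinary
development cycle.

## Known limitations

* The stepwise procedure inherits the usual instability of p-value-driven
  selection; the inclusion trace is returned so runs can be audited.
* The nearest-neighbour ROC estimator is not guaranteed monotone in the
  cutoff; the trapezoid is taken along the curve as parametrized, matching
  the reference implementation's behaviour.
* With independent noise candidates, the entry threshold of 0.05 admits at
  least one noise covariate in roughly 1−0.95^m of runs; this is a
  property of the prescribed thresholds, not a defect of the
  implementation.
* Bootstrap comparisons reuse the same resamples for both models, which is
  what makes the self-comparison p-value ≈ 1 and the test symmetric.
* Wrapper selection's headline AUC is the maximum over thousands of
  cross-validated evaluations and then over prefix models, so it carries a
  winner's-curse optimism even when every fold is clean: on fully null data
  at the recovery-run scale it lands above 0.75 in roughly a quarter of
  runs. The chosen subset's honest performance should be taken from an
  independent cohort (or nested CV), never from the selection curve.
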