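# sitesig

Discovery and evaluation of **site-specific transcriptomic prognostic
signatures** from bulk expression data and censored survival outcomes.

Gastric cancers arising at the cardia (gastro-oesophageal junction) and in
the distal (non-cardia) stomach differ epidemiologically and molecularly,
yet prognostic gene signatures are usually derived on pooled cohorts.
`sitesig` implements a fully site-separated discovery pipeline for
researchers working with expression matrices (FPKM-like gene, miRNA or
lncRNA quantifications) and survival annotations:

1. **Four-criterion biomarker filter** — per site, a feature is a candidate
   when call rate (fraction of samples with raw value > 0) > 0.70,
   |log2 fold change| (tumour vs normal, raw means) > 1, two-sided t-test
   p < 0.05 on log2(x+1) values, and univariate Cox p < 0.05 among the
   site's tumours.
2. **GA-SVM** — a genetic algorithm over binary feature-inclusion masks
   whose fitness is the 3-fold cross-validated AUC of a linear SVM,
   for tissue/site discrimination.
3. **GA-Cox** — the same engine with fitness equal to the 3-fold
   cross-validated *time-dependent* ROC AUC at 60 months of a multivariable
   Cox risk score.
4. **Consensus + forward selection** — features are ranked by their
   frequency in the 50 best subsets of the whole GA run, then prefixes of
   the ranking are evaluated and the prefix with maximal cross-validated
   AUC becomes the signature.
5. **Risk score** — one full-cohort Cox fit over the signature defines each
   patient's score ∑ βᵢXᵢ (Xᵢ = log2(x+1) expression); patients are split
   at the median score and compared by Kaplan–Meier/log-rank.
6. **Clinical and combined models** — p-value stepwise Cox (enter P < 0.05,
   remove P > 0.10) on clinical covariates; the combined model adds the
   risk score as one covariate; models are compared by bootstrap
   time-dependent ROC with a rank-sum test.
7. **Nomogram** — 0–100 point maps per covariate, total points → survival
   probability, with optimism-corrected C-index (1000 bootstrap resamples),
   calibration table and decision-curve analysis.

A seeded synthetic-data generator (`sim_config()`, `simulate_site_data()`)
produces FPKM-like zero-inflated expression with planted differential and
prognostic effects plus clinical covariates, so the whole pipeline is
testable without access to patient data.

## Worked example

```r
library(sitesig)

cfg <- sim_config(n_tumour = 200, n_normal = 32, n_features = 100,
                  n_de = 8, n_prog = 4, beta_prog = rep(0.8, 4), seed = 1)
ds  <- simulate_site_data(cfg)
res <- run_pipeline(ds$expression, ds$samples,
                    pipeline_config(site = "cardia",
                                    ga = ga_params(generations = 50,
                                                   pop_size = 50),
                                    max_k = 20, B = 1000, seed = 1))
print(res)
```

```
Site 'cardia' pipeline result
Filter report, site 'cardia': 4/100 features pass all four criteria
  call rate > 0.70: 100 | |log2FC| > 1: 9 | t p < 0.05: 14 | Cox p < 0.05: 9
GA-Cox signature (4 features): GENE_0003, GENE_0002, GENE_0004, GENE_0001
Log-rank test over 2 groups (100/100): chisq=72.847, df=1, p=1.4e-17
Site-specific prognostic models
  clinical covariates kept: radiation, neoplasm_status 
       model apparent_auc    cv_auc
 traditional    0.6143455 0.6227805
    combined    0.8999250 0.8941658
  ROC comparison (combined vs traditional): p = 0
C-index: apparent 0.824, adjusted 0.821 (95% CI 0.787-0.864)
```

The recovered signature is exactly the four planted prognostic features
(GENE_0001–GENE_0004). The median split separates survival at log-rank
p = 1.4e-17; the combined model's cross-validated time-dependent AUC (0.89)
clearly exceeds the clinical-only model (0.62) — the rank-sum p underflows
to zero — and the optimism-corrected C-index (0.82) shows the gain is not a
refitting artefact. (With only four candidates surviving the filter, the GA
archive is the exhaustive 15 subsets and a note says so.)
`plot(res$risk_model)`, `plot(res$nomogram)`, `plot(res$calibration)` and
`plot(res$decision)` draw the corresponding figures.

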