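# crlmrad

Baseline-CT radiomics survival pipeline for colorectal-cancer liver
metastases (CRLM).

Patients treated with chemotherapy and hepatectomy for resectable CRLM have
highly variable outcomes, and the preoperative Fong clinical risk score
(CRS, 0–5, dichotomized low 0–2 / high 3–5) captures only part of that
variation. `crlmrad` implements, end to end, a radiomics approach to
predicting **time to recurrence (TTR)** and **disease-specific survival
(DSS)** from baseline contrast-enhanced CT:

1. **Per-lesion feature extraction** — resampling to 1 mm isotropic voxels,
   clipping to [-100, 200] HU, 25 HU discretization, 1 mm crop; first-order,
   shape, GLCM and GLRLM features on the original and
   Laplacian-of-Gaussian (sigma 1–5 mm) channels; NIfTI in, CSV out.
   Externally computed full-catalog feature tables are ingested through the
   same schema.
2. **Multi-lesion aggregation** — seven strategies (largest/smallest lesion
   only, unweighted/weighted averages, weighted average of the three
   largest, largest + lesion count, largest + total volume); geometric
   features are summed across lesions, texture features averaged.
3. **Signature cascade** — per training subsample: MRMR top-50 →
   univariate Cox concordance filter (> 0.53) → cross-validated Lasso-Cox;
   repeated on 100 random 85% subsamples of the training set with
   per-feature selection counts; consensus signature
   `score = Σ βᵢ · featureᵢ`.
4. **Survival models** — a random survival forest (log-rank splitting) and
   a compact neural Cox model (two 4-unit blocks with batch-norm and
   dropout 0.1, full-batch Adam at 1e-5 minimizing the Breslow-ties
   negative Cox partial log-likelihood, early-stopped on a 15% validation
   split), both with or without CRS concatenated.
5. **Evaluation** — 15% event-stratified holdout; Harrell's concordance
   index for risk scores; landmark classification (TTR at 18 months, DSS at
   3 years) with logistic models on the scores; percentile-bootstrap
   confidence intervals (2000 iterations); built-in leakage audit.

A synthetic cohort generator with a known exponential proportional-hazards
structure (informative features planted in the largest lesion) and a 3-D
lesion phantom generator make every stage testable without clinical data.

## Worked example

```r
library(crlmrad)

# a 300-patient synthetic cohort: ~3 lesions/patient, 60 features,
# 3 informative at beta = 0.7/SD planted in the largest lesion
cohort <- generate_cohort(synthetic_config(seed = 7))
cohort
#> Synthetic CRLM cohort
#>   patients: 300   lesions: 924   features/lesion: 60
#>   TTR events: 192 (64%)   DSS events: 164 (55%)

report <- run_experiment(cohort, experiment_config(
  outcomes = "ttr", strategies = c("largest_only", "smallest_only"),
  models = "rsf", with_crs = FALSE, n_runs = 5, n_boot = 500, seed = 7))
subset(report$summary, metric == "cindex",
       select = c(strategy, model, estimate, ci_lo, ci_hi))
#>       strategy     model  estimate     ci_lo     ci_hi
#>           none       crs 0.6126761 0.6126761 0.6126761
#>   largest_only signature 0.8307298 0.8289373 0.8320102
#>   largest_only       rsf 0.8258643 0.8220230 0.8299616
#>  smallest_only signature 0.4801536 0.4571063 0.5032010
#>  smallest_only       rsf 0.4852753 0.4750320 0.4955186
```

Read: each row is the mean held-out metric over the repeated training
subsamples with its percentile-bootstrap interval. Aggregating by the
largest lesion recovers the planted prognostic signal (concordance ≈ 0.83
for both the Lasso-Cox signature and the forest, against 0.61 for the
clinical score alone), while the smallest-lesion strategy — which never
sees the informative lesion — stays near chance. Feature extraction from
images works the same way at lesion level:

```r
ph  <- generate_phantom(phantom_spec(radii_mm = c(8, 8, 8)), seed = 1)
rec <- extract_lesion(ph$image, ph$mask, preprocess_config())
rec
#> Lesion P0001/L01: volume 2176.0 mm3, 125 features
```

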