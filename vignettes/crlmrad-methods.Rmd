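---
title: "Methods: a baseline-CT radiomics survival pipeline for colorectal liver metastases"
author: "crlmrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a baseline-CT radiomics survival pipeline for colorectal liver metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Patients with resectable colorectal-cancer liver metastases (CRLM) face
widely varying outcomes after chemotherapy and hepatectomy, and the standard
preoperative tool — the Fong clinical risk score (CRS), five clinical
criteria summed to 0–5 and dichotomized low (0–2) / high (3–5) — leaves much
of that variation unexplained. `crlmrad` implements a full radiomics
alternative: texture and shape features computed from baseline
contrast-enhanced CT inside manually segmented lesion masks are aggregated
to the patient level, distilled into a prognostic signature, and fed to
survival models for time to recurrence (TTR) and disease-specific survival
(DSS), both right-censored at last follow-up and measured from curative
resection.

# Pipeline stages and their assumptions

## Image preprocessing and native features

Images and masks are resampled to 1×1×1 mm voxels (image: degree-1 B-spline,
i.e. trilinear; mask: nearest-neighbour, so labels stay binary), intensities
are clipped to the [-100, 200] HU soft-tissue window, discretized with a
fixed 25 HU bin width (12 bins; the top clip value joins the top bin so no
empty 13th bin exists), and both volumes are cropped 1 mm around the lesion.
Texture is computed on the original channel and on Laplacian-of-Gaussian
(LoG) channels at sigma 1–5 mm; LoG runs after resampling so sigma in mm
equals sigma in voxels, with reflective boundaries and a sigma² scale
normalization that makes responses comparable across the sigma grid.

The native catalog is deliberately a verifiable subset: 10 first-order
statistics, 5 GLCM and 5 GLRLM features per channel plus 5 shape features
(125 features at the default five sigmas). Texture matrices use the 13
antipodal-unique 3-D directions at distance 1 voxel, each direction
normalized separately and features averaged unweighted across directions —
the most common convention where the field's tooling differs. Full
1,317-feature tables produced by external engines (wavelet channels,
GLSZM/NGTDM/GLDM families) enter through `ingest_feature_table()` instead of
being recomputed; the analysis pipeline downstream is identical either way.
One deliberate assumption: the same clip-window/bin-width rule is applied to
every channel, including LoG outputs whose units are not HU; a fixed rule
keeps discretization comparable across channels and is flagged here because
published pipelines are silent on it.

Degenerate lesions (fewer than 2 voxels after resampling) keep shape and
first-order features with texture features set `NA` and a warning, rather
than failing the whole extraction.

## Multi-lesion aggregation and the clinical score

Most patients have several metastases; `aggregate_lesions()` implements
seven patient-level reductions: largest lesion only, smallest lesion only,
unweighted average, volume-ratio-weighted average, weighted average of the
three largest lesions (ratios renormalized over the three), and largest
lesion plus either the lesion count or the total metastatic volume. In every
multi-lesion strategy geometric (shape/burden) features are summed while
texture features are averaged. First-order intensity statistics are classed
as texture (averaged) — the taxonomy is a configurable map because that
choice is a convention, not a law. Volume ties are broken by lexicographic
lesion id so aggregation is deterministic.

`fong_crs()` awards one point each for node-positive primary, disease-free
interval under 12 months, more than one metastasis, largest lesion over
5 cm, and CEA over 200 ng/mL — strict inequalities exactly as published, so
boundary values score nothing.

## The signature cascade

Feature selection runs entirely inside the training partition. Each of 100
runs draws a random 85% subsample of the training set and applies, in order:

1. **MRMR** (difference criterion) down to the top 50 features. The
   relevance target is the event indicator with quartile-discretized
   features — the choice of target is undocumented in the surrounding
   literature, so it is explicit configuration here.
2. **Univariate Cox filter**: one-covariate proportional-hazards fits
   (Breslow ties); a feature survives iff the training concordance of its
   fitted risk score exceeds 0.53. Applied per-run.
3. **Lasso-Cox** (`glmnet`), features standardized internally, penalty
   chosen by 5-fold cross-validated partial likelihood (`lambda.min`; the
   one-standard-error rule is off by default because no rule is prescribed).

Per-feature selection counts and coefficients are traced across runs; the
consensus signature keeps features selected in at least half the runs (a
configurable fraction) with their mean coefficients, and scores a patient by
plain linear combination.

## Survival models

Two models consume the selected features, optionally with the dichotomized
CRS concatenated as one extra 0/1 column:

* **Random survival forest** — log-rank splitting over bootstrap samples
  (`ranger`), 200 trees, √d features per split, minimum terminal node 5; a
  patient's risk is the ensemble cumulative hazard summed over the unique
  event times. The defaults are conventional and exposed, since forests of
  this kind overfit small cohorts easily.
* **Compact neural Cox model** — input → [4-unit linear → batch-norm → ReLU
  → dropout 0.1] × 2 → linear risk output, trained full-batch with Adam at
  learning rate 1e-5 on the Breslow-ties negative Cox partial
  log-likelihood averaged over events. Full-batch steps avoid the risk-set
  truncation bias that mini-batching introduces into the partial
  likelihood. Training stops at the lowest loss on an internal 15%
  validation split (stratified by event status); the returned model is the
  weights snapshot at that minimum.

Two numerical choices matter at this learning rate. First, with Adam's
per-coordinate step bounded near the learning rate, meaningful movement
takes tens of thousands of full-batch epochs; the defaults are
`max_epochs = 30000`, `patience = 3000`, which on cohorts of a few hundred
patients train in tens of seconds. Second, batch-norm running statistics
are initialized from the first batch rather than (0, 1): with cold
statistics the epoch-1 validation loss is computed under arbitrary
normalization, can be a spurious minimum, and freezes early stopping before
training starts. Inputs are standardized with training-set mean/SD, frozen
for later scoring; evaluation mode disables dropout and uses the running
statistics, so prediction is deterministic.

## Evaluation design

One stratified holdout (15% of the cohort, event ratio matched by
stratified sampling on the event flag; `round(0.15 × 241) = 36` for a
241-patient cohort) is drawn per outcome; the remaining training set feeds
the 100 subsampled runs. A runtime audit asserts that holdout indices never
intersect any training subsample.

Survival performance is Harrell's concordance on the holdout — a pair is
comparable iff the strictly earlier time is an event, tied scores earn half
credit. Classification dichotomizes the outcome at a landmark (18 months
for TTR, 36 months for DSS): events at or before the horizon are positive,
observations reaching the horizon are negative, and patients censored
before the horizon are excluded from classifier fitting and AUC — the
landmark convention, with exclusion counts recorded. A logistic model maps
training-set survival scores (plus optionally CRS) to class probabilities
and is applied to the holdout; AUC is the tie-aware rank statistic. Direct
logistic and random-forest classifiers on the raw selected features serve
as baselines.

Point estimates are means over the per-run holdout metrics; confidence
intervals are percentile bootstraps (default 2000 iterations) over those
per-run values. How the original 100-run design collapses into one interval
is genuinely underdetermined — bootstrapping patients, runs, or both are
all defensible; this package bootstraps the run-level metrics and says so
in the report schema, rather than guessing at intent.

# The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws per-patient lesion counts as 1 + Poisson(2) (mean
3, matching the scale of reported CRLM counts), log-normal lesion volumes,
and per-lesion features as equicorrelated Gaussian blocks (correlation 0.3
in blocks of 10) so that noise features correlate with informative ones and
selection is non-trivial. Three informative features (reserved names
`inf_01..inf_03`, coefficients 0.7 per SD) plus 0.4 for a high CRS form the
hazard linear predictor; crucially the signal is planted in the **largest**
lesion, so largest-lesion aggregation can recover it and smallest-lesion
aggregation cannot — the qualitative structure reported for real CRLM
cohorts. TTR and DSS are exponential proportional-hazards draws (baseline
0.02/month for TTR, half that for DSS) with censoring from an independent
exponential (0.006/month) truncated at an 84-month horizon, which lands
near 35% censoring; the true censoring pattern of registry cohorts is not
published, so these are stated defaults, not estimates. Clinical fields are
sampled so the Fong score concentrates on 2–3, mirroring the published
distribution's shape.

What the generator does **not** emulate: scanner and reconstruction-kernel
heterogeneity, non-proportional hazards, informative censoring,
within-patient lesion correlation beyond the volume/signal link, and any
relation between the synthetic feature columns and actual image texture.
Passing tests on this cohort therefore demonstrate that the pipeline's
machinery is correct and leak-free and that it recovers planted
proportional-hazards signal at realistic size and censoring — not that the
published real-data effect sizes are reproducible.

The exponential survival law was chosen over Weibull because every check
(event-rate, mean time, oracle concordance) then has a closed form; the
config structure leaves room for a Weibull extension.

# Problem sizes used by the shipped checks

The packaged checks run the full design at reduced scale, chosen so each
stage is still exercised meaningfully: recovery experiments use the default
n = 300 cohort with 10 subsampled runs and both models; the
strategy-ordering comparison uses 10 independent cohorts of n = 260 with a
forest scorer; bootstrap coverage uses 200 replicates of n = 100 at 2000
resamples; exactness checks (metrics, texture matrices, Cox machinery)
enumerate small instances where brute force is feasible (grids ≤ 5×5×5,
datasets ≤ 8 subjects, cohorts ≤ 60). The acceptance script reports
held-out metrics from 5 runs per cell.

# Known limitations

* The native feature set is a verifiable subset, not the full catalog of
  production radiomics engines; IBSI certification is out of scope.
* Trilinear rather than cubic B-spline resampling shifts interpolated
  values slightly; shape features are unaffected (masks are
  nearest-neighbour either way).
* `cv.glmnet`'s fold assignment consumes RNG, so signatures are
  reproducible only through the seed plumbing used by
  `repeated_signature()` / `run_experiment()`.
* The neural model is a minimal backbone; no hyperparameter search is
  performed beyond the exposed configuration.
* DICOM ingestion and inter-scanner harmonization (e.g. ComBat) are out of
  scope; NIfTI is the only image format read.
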