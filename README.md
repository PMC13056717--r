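# braingap

Multilevel grey-matter brain-age modelling and brain-age-gap inference in R.

Structural MRI studies increasingly summarize grey-matter ageing as a single
biomarker: a model trained on healthy brains predicts each person's age from
their grey-matter-volume (GMV) pattern, and the **brain-age gap (BAG)** —
bias-corrected predicted age minus chronological age — measures how much
older (positive) or younger (negative) a brain appears than its owner.
`braingap` implements this analysis at two levels for clinical case-control
studies (its defaults mirror a migraine-versus-control design, but nothing is
condition-specific):

* **Global**: one SVR-RBF model on the mean GMV of 442 atlas parcels
  (400 cortical + 14 subcortical + 28 cerebellar), trained with nested
  5-fold cross-validation and grid search over C and gamma in 0.001–1000.
* **Regional**: one SVR-RBF model per parcel on that parcel's voxel-wise
  GMV, giving a per-parcel BAG map.

Around the models the package provides the full inferential chain:

* regression-to-the-mean **bias correction**,
  `corrected = predicted + (age − (α + β·age))`, with the bias regression
  estimated on an independent normative calibration cohort;
* covariate-adjusted **ANCOVA** (age, age², sex, TIV, protocol) with partial
  eta squared, Benjamini–Hochberg **FDR** across the 442 parcels, **ComBat**
  protocol harmonization and protocol-stratified comparison;
* **permutation CCA** linking regional BAG patterns (PCA-reduced to 50%
  variance) to clinical profiles, with step-down Wilks statistics,
  max-statistic FWE-corrected loadings, and bootstrap stability intervals;
* meta-analytic **functional decoding** of affected regions against a
  labelled activation-foci database
  (`Z = (k − n·p0)/√(n·p0(1−p0))`, significant at Z > 3.0);
* a **synthetic cohort generator** with recoverable ground truth (regional
  atrophy rates, a shared per-subject ageing deviation, sex/TIV/protocol
  structure, and a latent clinical severity factor), so the entire pipeline
  is testable end to end; NIfTI emission/extraction round-trips exactly.

Everything is tibble-first: results come back as tibbles or as objects with
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Train a global model on a normative cohort, calibrate the bias correction,
and test a clinical cohort in which 20 of 120 parcels age 4 years faster:

```r
library(braingap)
library(dplyr)

train  <- generate_normative_cohort(cohort_config(300, n_regions = 120, seed = 1))
spec   <- model_spec(cost_grid = c(1, 10, 100), gamma_grid = c(0.001, 0.01, 0.1))
models <- fit_final_models(train$region_means, train$subjects$age, spec = spec)

cal  <- generate_normative_cohort(cohort_config(200, n_regions = 120, seed = 2))
bias <- fit_bias_models(models, region_means = cal$region_means,
                        ages = cal$subjects$age)$global
bias
#> <bias_model> predicted = 8.873 + 0.854 * age (n = 200, sigma = 4.46)

cfg  <- cohort_config(180, n_regions = 120, seed = 3)
eff  <- effect_spec(default_affected_regions(cfg, 20), bag_shift = 4)
clin <- generate_clinical_cohort(cfg, eff)

pred <- predict_brain_age(models, region_means = clin$region_means)
bag  <- correct_and_bag(bias, pred$global, clin$subjects$age)
ancova_compare(mutate(clin$subjects, bag = bag$bag))
#> <ancova_result> F(1, 173) = 3.723, p = 0.05529, eta_p^2 = 0.021
#>   adjusted difference (patient - control) = 1.354 y, 95% CI (-0.03, 2.74)
```

The bias slope 0.854 quantifies the regression-to-the-mean every brain-age
model shows (raw predictions are compressed toward the training mean; the
correction removes the resulting age-dependence of the gap). The adjusted
difference of 1.35 years is the patients' extra apparent ageing at the
global level: the 4-year regional effect is diluted because only 20 of 120
parcels carry it. Per-parcel localization of the effect uses the regional
models with `regional_ancova()` and FDR selection, and `permcca()` relates
the selected parcels' BAGs to the clinical profile.

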