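---
title: "Multilevel grey-matter brain-age modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel grey-matter brain-age modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`braingap` implements a multilevel grey-matter brain-age analysis. The
pipeline consumes spatially normalized, modulated grey-matter-volume (GMV)
maps together with an integer-labelled parcellation (442 parcels by default:
400 cortical, 14 subcortical, 28 cerebellar) and a grey-matter probability
mask, and proceeds in five stages:

1. **Feature extraction** (`build_gm_mask()`, `extract_features()`). Voxels
   with grey-matter probability strictly above 0.2 are retained; per parcel,
   the pipeline keeps both the *mean* GMV (input to the global model) and the
   *voxel-wise* GMV vector (input to that parcel's regional model). Voxels
   are scanned in the array's native column-major linear order, fixed so
   voxel columns are comparable across subjects. Parcels fully removed by
   the mask are dropped and reported; downstream model counts adapt.

2. **Brain-age models** (`model_spec()`, `nested_cv_train()`,
   `fit_final_models()`, `predict_brain_age()`). Support vector regression
   with an RBF kernel predicts chronological age, one global model on the
   442 parcel means and one regional model per parcel on its voxels. Nested
   cross-validation separates hyperparameter selection (inner folds, grid
   search over cost and kernel width on a logarithmic 0.001--1000 range)
   from performance estimation (outer folds), so no out-of-fold prediction
   touches a model that saw that subject. Folds are stratified by age
   quantile bins with equal sizes (+/-1). Features are standardized with
   means/sds learned on the training folds only; RBF kernels are
   scale-sensitive and leaving features unscaled would let high-variance
   parcels dominate. Grid ties resolve toward smaller cost, then smaller
   kernel width (the simpler model). The epsilon-insensitive tube half-width
   stays at the conventional 0.1 (years).

3. **Bias correction and BAG** (`fit_bias_model()`, `correct_and_bag()`,
   `bag_table()`). Predicted brain age regresses toward the training mean:
   the regression of predicted on chronological age has slope < 1, so raw
   brain-age gaps correlate negatively with age. The correction is the
   additive-offset form `corrected = predicted + (age - (alpha + beta*age))`;
   the rescaling form `(predicted - alpha)/beta` is available behind
   `method = "rescale"` for sensitivity analysis (it amplifies noise when
   the slope is small). BAG = corrected minus chronological age; positive
   values mean an older-appearing brain.

   The bias parameters are estimated from *final-model predictions on an
   independent normative calibration cohort*, not from the training
   cross-validated predictions. Fold models (trained on 80% of the data)
   are systematically more attenuated than the final model, so a CV-based
   slope under-corrects new data; estimating the regression where it will
   be applied — new normative subjects, final model — makes held-out BAG
   mean-zero and age-uncorrelated. The CV-based fallback remains available
   (`fit_bias_models()` without calibration arguments).

4. **Group inference** (`ancova_compare()`, `regional_ancova()`,
   `fdr_select()`, `combat_harmonize()`, `stratified_compare()`). BAG is
   compared between groups by ANCOVA adjusting for age, centred-age squared
   (centring limits collinearity between the linear and quadratic terms),
   sex, total intracranial volume and acquisition protocol. Effect size is
   partial eta squared, `SS_group / (SS_group + SS_residual)`; the adjusted
   difference carries a Wald t interval. Regional tests run across all 442
   parcels with Benjamini--Hochberg FDR control; selection uses
   `p_adj <= q`, which is exactly the classical step-up rule (a strict `<`
   would drop boundary cases the step-up procedure admits).
   Benjamini--Hochberg rather than Benjamini--Yekutieli is standard for
   parcel-wise neuroimaging tests, whose dependence is predominantly
   positive. ComBat (parametric empirical-Bayes location-scale
   harmonization, with a non-EB mode) removes protocol effects while
   preserving a biological design; three-or-more-level group comparisons
   reuse the same linear-model machinery with an omnibus F and unadjusted
   pairwise contrasts.

5. **Clinical association and decoding** (`permcca()`,
   `loading_inference()`, `bootstrap_stability()`, `region_contributions()`,
   `decode_roi()`). The link between regional BAG patterns and the clinical
   profile (headache frequency, painkiller frequency, MIDAS, BDI, disease
   duration) is a canonical correlation analysis with permutation inference.
   Both sets are residualized on their confounds (age and sex for the
   clinical set; age, age squared, sex, TIV and protocol for the imaging
   set), the imaging set is PCA-reduced to 50% explained variance, and each
   mode is tested by permuting subject rows of the residualized clinical set
   with the step-down Wilks statistic `-sum_{j>=m} log(1 - r_j^2)`.
   P-values use the +1 convention; ties count as exceedances; at tiny n the
   test switches to exhaustive enumeration of all row orders. Loadings
   (correlations of each clinical variable with the mode-1 clinical variate)
   get family-wise-error control from the max-statistic permutation
   distribution computed against the *fixed* observed variate — refitting
   the CCA per permutation would make null loadings large by construction,
   since a variate is always a combination of its own set's columns.
   Bootstrap stability resamples subjects, re-residualizes, projects onto
   the *original* PCA basis (component-order instability would otherwise
   dominate the loading intervals) and sign-aligns each replicate to the
   observed variate before forming percentile intervals. Mode signs are
   fixed so the largest-magnitude clinical loading is positive.

   Functional decoding compares the proportion of labelled activation foci
   inside a binary ROI mask against each behavioural sub-domain's base rate
   in the whole database: with n in-ROI foci and base rate p0,
   `Z = (k - n*p0) / sqrt(n*p0*(1-p0))`, with a two-sided exact binomial p
   co-reported so the normal approximation is auditable, and the fixed
   decision rule Z > 3.0 (Bonferroni-level control across 59 sub-domains).
   Foci map to voxels by rounding through the inverse affine; an optional
   dilation radius (mm) relaxes the nearest-voxel rule. Mask and database
   must carry the same stereotaxic-space tag; no Talairach/MNI conversion
   is attempted.

# The synthetic cohort generator

No public cohort accompanies this analysis, so `generate_normative_cohort()`
and `generate_clinical_cohort()` produce cohorts with the statistical
structure the pipeline assumes, plus recoverable ground truth. Per subject
s and parcel r,

```
mean_GMV[s, r] = scale_site * (TIV_s/1430)^0.2 *
                 (baseline_r - slope_r * (age_s + delta_s) + sex_term_s)
                 + shift_site + Normal(0, noise_sd)
```

with voxel features equal to the parcel mean plus fixed voxel offsets plus
voxel noise (both centred, so voxel averages reproduce the parcel mean
exactly and emitted NIfTI files round-trip through `extract_features()`).

Key choices, with units and rationale:

* **Ages**: truncated normal on 20--92 y (midpoint mean, sd = range/4.8
  ~ 15 y). Volunteer cohorts are bell-shaped, not flat (clinical-cohort age
  sds near 10 y are typical), and the sparse tails reproduce the
  edge-of-range compression that real brain-age models show. A `"uniform"`
  option is retained.
* **Atrophy rates** `slope_r`: 0.0003--0.0028 a.u./year on a sin-squared
  profile across parcels — both weakly and strongly ageing parcels exist,
  matching the wide spread of regional model accuracies reported for
  parcel-wise brain-age models.
* **Ageing dispersion** `delta_s` ~ Normal(0, 5.5 y), shared across all
  parcels of a subject and mean-centred per cohort. This is the biological
  quantity a brain-age model cannot remove — it *is* the brain-age gap of a
  healthy brain. 5.5 y is calibrated so the desk-scale global model lands
  near published performance (R^2 ~ 0.82--0.87, MAE ~ 4--5 y at n = 600):
  residual sd = age sd x sqrt(1 - R^2) ~ 6 y, of which ~2.5 y is model
  error. Mean-centring per cohort is a variance-reduction choice: cohorts
  are exchangeable with the normative population by construction, so
  finite-cohort drift does not confound calibration checks.
* **TIV**: Normal(1430, 120) mL, entering through a mild exponent 0.2.
  The pipeline consumes spatially normalized modulated maps, in which head
  size is largely divided out; full multiplicative TIV scatter would bury
  each parcel's age signal in ~15 equivalent years of head-size noise that
  no covariate can remove at the feature level.
* **Protocols**: two scanners (26% / 74% sampling) with a small additive
  offset (0.006 a.u.) and scale (1.02) on the minority protocol — enough
  structure for the protocol covariate, ComBat and the stratified analysis
  to have real work to do.
* **Sex**: Bernoulli(0.65 female) and a small additive male offset
  (0.004 a.u.).
* **Clinical coupling**: patients carry a latent severity ~ |Normal(1, 0.5)|
  (controls 0). Affected parcels lose `slope_r * bag_shift * severity`
  a.u. — exactly `bag_shift * severity` years of equivalent extra ageing.
  Clinical variables are `baseline + loading * severity + noise`, truncated
  to valid ranges (0--30 days/month for frequencies; MIDAS and BDI use
  mean-zero lognormal-derived noise, giving the long right tail their
  published medians/IQRs imply). Default loadings (8, 4, 0, 6, 0 units per
  severity for headache frequency, painkiller frequency, MIDAS, BDI,
  duration) couple three of five variables, mirroring a multivariate — not
  univariate — clinical association. The default affected set is the 66
  strongest-ageing parcels: clinically accelerated ageing is measurable
  only where ageing itself is, and reported effects concentrate in strongly
  ageing cortex. Per-parcel effect magnitudes beyond this profile are a
  user choice, not a calibrated quantity.

Because every deterministic term is invertible, `deviation_years()` maps a
bundle back to age-equivalent deviations (`bag_shift * severity + delta +
noise/slope` in affected parcels), `expected_bag_difference()` gives the
analytic group difference implied by the stored truth (regionally
`gain * bag_shift * mean(severity)`; globally diluted by the precision share
of the affected parcels, with `gain` the bias-model slope under the additive
correction), and `population_canonical_correlation()` gives the closed-form
population canonical correlation of the single-latent-factor design
(`rho = rho_clinical * rho_imaging`, each factor the maximal correlation of
one set with the latent severity; range truncation is ignored, a slight
overestimate).

What the generator does *not* emulate: cortical geometry and spatial
autocorrelation, segmentation and registration error, scanner drift,
non-linear ageing trajectories, site-by-age interactions, and missingness.
Passing tests therefore demonstrate the statistical machinery — fold
hygiene, bias-correction algebra, error control, permutation validity,
recovery of known effects — on data with the assumed structure, not
robustness to the artefacts of real MRI.

# Desk-scale study sizes

The test-suite and `scripts/acceptance.R` run the full pipeline at sizes a
laptop handles in minutes, chosen as the package's standard desk-scale
conditions: global model trained on n = 600 with a 4 x 4 powers-of-ten grid
spanning 0.001--1000; regional models on n = 420 with a 3 x 3 grid
(1--100 x 0.01--1); bias calibration cohort n = 400; held-out evaluation
n = 200; clinical cohorts of 180 (110 patients : 70 controls); permutation
and bootstrap counts of 500--1000 (scaled down from the 10 000 a full
analysis would use; at 1000 the smallest attainable two-sided p is ~0.001,
ample for calibration checks).

# Numerical and degenerate-input choices

* Constant feature columns standardize with sd 1 and a warning; a constant
  *target* leaves the SVR with no support vectors, and predictions fall
  back to the tube centre (the target mean).
* Duplicate-subject refits agree only to ~1e-4 relative: the solver stops
  at a 1e-3 duality gap and the epsilon-tube optimum is a set, not a point.
* BH selection at the boundary uses `p_adj <= q` (step-up equivalence).
* ComBat empirical-Bayes shrinkage needs >= 2 features; single-feature
  input (global BAG) automatically uses the unshrunk location-scale
  estimates. Batches need >= 2 subjects.
* Permutation p-values can never be 0 (+1 convention); exhaustive
  enumeration replaces sampling when n! <= nperm.
* PCA keeps the smallest k whose cumulative explained variance reaches the
  target (with a 1e-12 slack against ties); zero-variance inputs error.
* Bootstrap replicates with degenerate covariance are skipped and counted;
  more than 5% skipped raises a warning.
* Foci with coordinates outside the mask grid are simply out-of-ROI;
  sub-domains with zero database count are skipped and listed.

# Known limitations

* The SVR pass-through of an injected feature-space effect is slightly
  attenuated (by roughly the bias slope); `expected_bag_difference()`
  accounts for this with its `gain` argument, but the precision-weighting
  argument it uses is an approximation to what a kernel model actually
  does.
* The shared ageing dispersion makes regional test statistics correlated
  across parcels within a replicate: an adverse patient/control draw of the
  dispersion shifts all parcels together, occasionally sinking a whole
  replicate below the FDR selection threshold at n = 110 vs 70. This is a
  real property of such designs, not an artefact.
* Complete-case analysis only for the clinical CCA; no imputation.
* Only the first canonical mode is interpreted; later modes are tested
  (step-down) but not decomposed further.
* The PCA-before-CCA order operates on residualized BAG; the alternative
  order (PCA on raw BAG) is not currently exposed.
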