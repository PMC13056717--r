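#' Configuration for a synthetic GMV cohort
#'
#' Defines the generative model for a cohort of subjects with per-region mean
#' grey-matter volume (GMV) and per-region voxel-wise GMV features. Regional
#' GMV declines linearly with age at a region-specific rate; individual brains
#' additionally age faster or slower than their chronological age by a shared
#' "ageing deviation" (the biological quantity a brain-age gap estimates),
#' and acquisition protocol, sex and total intracranial volume (TIV) add
#' location/scale structure.
#'
#' @param n_subjects number of subjects (>= 10).
#' @param age_range numeric length-2, min < max, in years.
#' @param age_dist `"normal"` (default): ages follow a truncated normal
#'   centred on the range midpoint with sd = range/4.8, the bell-shaped age
#'   structure of real volunteer cohorts; `"uniform"`: flat over the range.
#' @param n_regions number of atlas parcels (default 442).
#' @param voxels_per_region voxels simulated per parcel (>= 1).
#' @param sites data frame with columns `protocol`, `prob`, `shift`, `scale`:
#'   acquisition protocols with sampling probability, additive offset (a.u.)
#'   and multiplicative scale applied to region means.
#' @param sex_effect additive male-minus-female offset on region means (a.u.).
#' @param tiv_coupling exponent of the multiplicative TIV scaling
#'   `(TIV / 1430)^tiv_coupling`; 0 disables TIV effects. The default 0.2
#'   reflects the mild residual head-size association of spatially
#'   normalized, modulated GMV maps (full TIV scaling is removed by MNI
#'   normalization upstream of this pipeline).
#' @param noise_sd region-level measurement/biological noise sd (a.u., >= 0).
#' @param voxel_noise_sd voxel-level noise sd around the region mean (a.u.).
#' @param ageing_dispersion sd (years) of the per-subject shared ageing
#'   deviation; drawn mean-zero within each cohort so that cohorts are
#'   exchangeable with the normative population.
#' @param prop_female probability that a subject is female.
#' @param seed integer RNG seed; generation is deterministic given the seed.
#'
#' @return an object of class `cohort_config`.
#' @seealso [generate_normative_cohort()], [generate_clinical_cohort()]
#' @export
cohort_config <- function(n_subjects,
                          age_range = c(20, 92),
                          age_dist = c("normal", "uniform"),
                          n_regions = 442,
                          voxels_per_region = 8,
                          sites = default_sites(),
                          sex_effect = 0.004,
                          tiv_coupling = 0.2,
                          noise_sd = 0.004,
                          voxel_noise_sd = 0.004,
                          ageing_dispersion = 5.5,
                          prop_female = 0.65,
                          seed = 1L) {
  assert_scalar_number(n_subjects, "n_subjects", min = 10)
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      !all(is.finite(age_range)) || age_range[1] >= age_range[2]) {
    bg_stop("invalid configuration: `age_range` must be (min, max) with min < max",
            class = "braingap_config_error")
  }
  assert_scalar_number(n_regions, "n_regions", min = 1)
  assert_scalar_number(voxels_per_region, "voxels_per_region", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(voxel_noise_sd, "voxel_noise_sd", min = 0)
  assert_scalar_number(ageing_dispersion, "ageing_dispersion", min = 0)
  assert_scalar_number(sex_effect, "sex_effect", min = -Inf)
  assert_scalar_number(tiv_coupling, "tiv_coupling", min = -Inf)
  assert_scalar_number(seed, "seed", min = -Inf)
  age_dist <- match.arg(age_dist)
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("protocol", "prob", "shift", "scale") %in% names(sites)))
  structure(
    list(n_subjects = as.integer(n_subjects), age_range = age_range,
         age_dist = age_dist, n_regions = as.integer(n_regions),
         voxels_per_region = as.integer(voxels_per_region),
         sites = sites, sex_effect = sex_effect, tiv_coupling = tiv_coupling,
         noise_sd = noise_sd, voxel_noise_sd = voxel_noise_sd,
         ageing_dispersion = ageing_dispersion, prop_female = prop_female,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default acquisition protocols
#'
#' Two protocols with a small location/scale offset, mirroring a two-scanner
#' study design (a minority inversion-recovery protocol and a majority
#' gradient-echo protocol).
#' @return tibble with columns protocol, prob, shift, scale.
#' @export
default_sites <- function() {
  tibble::tibble(protocol = c("IR-FSPGR", "BRAVO"),
                 prob = c(0.26, 0.74),
                 shift = c(0.006, 0),
                 scale = c(1.02, 1))
}

#' Fixed per-region generative parameters
#'
#' Baseline GMV and annual atrophy rate per parcel. These are deterministic
#' functions of the region index (not of the cohort seed) so that models
#' trained on one cohort transfer to any other cohort of the same
#' configuration. Atrophy rates follow a sin-squared profile, giving both
#' weakly and strongly ageing parcels, as seen across cortical,
#' subcortical and cerebellar regions.
#'
#' @param n_regions number of parcels.
#' @return tibble with columns `region` (label), `baseline` (a.u.) and
#'   `slope` (a.u. lost per year).
#' @export
region_parameters <- function(n_regions) {
  r <- seq_len(n_regions)
  tibble::tibble(
    region = sprintf("R%03d", r),
    baseline = 0.55 + 0.12 * sin(3 * 2 * pi * r / n_regions),
    slope = 0.0003 + 0.0025 * sin(pi * (r - 0.5) / n_regions)^2)
}

#' Group-effect specification for a clinical cohort
#'
#' Patients receive an extra GMV decrement in `affected_regions` equivalent to
#' `bag_shift` years of additional ageing, scaled by a per-patient latent
#' severity (|Normal(1, 0.5)|; controls have severity 0). Clinical variables
#' are linearly coupled to the same latent severity.
#'
#' @param affected_regions integer indices of affected parcels.
#' @param bag_shift years of equivalent extra ageing in affected parcels.
#' @param latent_loadings named numeric length 5: units of each clinical
#'   variable per unit latent severity, in the order headache_freq,
#'   painkiller_freq, midas, bdi, duration_years.
#' @param clinical_noise_sd named numeric length 5: residual sd per variable.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(affected_regions,
                        bag_shift = 4,
                        latent_loadings = c(headache_freq = 8, painkiller_freq = 4,
                                            midas = 0, bdi = 6, duration_years = 0),
                        clinical_noise_sd = c(headache_freq = 4, painkiller_freq = 2.5,
                                              midas = 15, bdi = 4, duration_years = 6)) {
  if (!is.numeric(affected_regions) || anyNA(affected_regions)) {
    bg_stop("`affected_regions` must be integer region indices",
            class = "braingap_config_error")
  }
  assert_scalar_number(bag_shift, "bag_shift", min = -Inf)
  stopifnot(length(latent_loadings) == 5L, length(clinical_noise_sd) == 5L,
            all(clinical_noise_sd >= 0))
  structure(list(affected_regions = as.integer(affected_regions),
                 bag_shift = bag_shift,
                 latent_loadings = latent_loadings,
                 clinical_noise_sd = clinical_noise_sd),
            class = "effect_spec")
}

#' Default affected-region set
#'
#' The parcels with the strongest ageing signal (largest atrophy slope),
#' where clinically accelerated ageing is measurable -- mirroring reports of
#' effects concentrated in strongly ageing cortical regions.
#'
#' @param config a [cohort_config()].
#' @param n_affected number of affected parcels (default 66).
#' @return integer vector of region indices.
#' @export
default_affected_regions <- function(config, n_affected = 66) {
  rp <- region_parameters(config$n_regions)
  sort(order(rp$slope, decreasing = TRUE)[seq_len(n_affected)])
}

# folded-normal moments for severity ~ |N(mu, sd)|
folded_normal_moments <- function(mu = 1, sd = 0.5) {
  m <- sd * sqrt(2 / pi) * exp(-mu^2 / (2 * sd^2)) +
    mu * (1 - 2 * pnorm(-mu / sd))
  v <- mu^2 + sd^2 - m^2
  list(mean = m, var = v)
}

# mean-zero right-skewed noise derived from a lognormal, sd = `sd`
skew_noise <- function(n, sd, lsd = 0.8) {
  raw <- exp(rnorm(n, 0, lsd))
  m1 <- exp(lsd^2 / 2)
  v1 <- (exp(lsd^2) - 1) * exp(lsd^2)
  sd * (raw - m1) / sqrt(v1)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic within-region voxel offsets, centred so that the mean of the
# voxel features equals the region mean exactly
voxel_offsets <- function(r, n_voxels) {
  off <- 0.03 * cos(2 * pi * seq_len(n_voxels) / n_voxels + r)
  off - mean(off)
}

# cohort age draw: bell-shaped (truncated normal) by default, or uniform
draw_ages <- function(n, config) {
  lo <- config$age_range[1]; hi <- config$age_range[2]
  if (identical(config$age_dist, "uniform")) return(runif(n, lo, hi))
  mu <- (lo + hi) / 2
  sd_a <- (hi - lo) / 4.8
  out <- numeric(0)
  while (length(out) < n) {
    a <- rnorm(2L * (n - length(out)) + 10L, mu, sd_a)
    out <- c(out, a[a >= lo & a <= hi])
  }
  out[seq_len(n)]
}

# shared generation core; `severity` is per-subject (0 for controls)
generate_core <- function(config, effect = NULL, group = NULL, severity = NULL) {
  set.seed(config$seed)
  n <- config$n_subjects
  rp <- region_parameters(config$n_regions)
  age <- draw_ages(n, config)
  sex <- ifelse(runif(n) < config$prop_female, "F", "M")
  tiv <- rnorm(n, 1430, 120)
  proto_idx <- sample.int(nrow(config$sites), n, replace = TRUE,
                          prob = config$sites$prob)
  protocol <- config$sites$protocol[proto_idx]
  delta <- rnorm(n, 0, config$ageing_dispersion)
  if (config$ageing_dispersion > 0) delta <- delta - mean(delta)

  if (is.null(group)) group <- rep("control", n)
  if (is.null(severity)) severity <- numeric(n)

  tivfac <- (tiv / 1430)^config$tiv_coupling
  sexterm <- config$sex_effect * (sex == "M")
  s_scale <- config$sites$scale[proto_idx]
  s_shift <- config$sites$shift[proto_idx]

  # effective ageing position: chronological age + shared deviation
  # (+ equivalent extra ageing in affected regions for patients)
  eff_age <- age + delta
  M <- outer(rep(1, n), rp$baseline) - outer(eff_age, rp$slope) + sexterm
  if (!is.null(effect) && effect$bag_shift != 0) {
    for (r in effect$affected_regions) {
      M[, r] <- M[, r] - rp$slope[r] * effect$bag_shift * severity
    }
  }
  M <- (s_scale * tivfac) * M + s_shift
  M <- M + matrix(rnorm(n * config$n_regions, 0, config$noise_sd), n)
  colnames(M) <- rp$region

  # voxel features: region mean + centred offsets + centred voxel noise, so
  # that the voxel average reproduces the region mean exactly
  vox <- lapply(seq_len(config$n_regions), function(r) {
    eps <- matrix(rnorm(n * config$voxels_per_region, 0, config$voxel_noise_sd),
                  n, config$voxels_per_region)
    eps <- eps - rowMeans(eps)
    sweep(eps, 2, voxel_offsets(r, config$voxels_per_region), "+") + M[, r]
  })
  names(vox) <- rp$region

  subjects <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)), age = age, sex = sex, group = group,
    protocol = protocol, tiv_ml = tiv,
    headache_freq = NA_real_, painkiller_freq = NA_real_,
    midas = NA_real_, bdi = NA_real_, duration_years = NA_real_)

  structure(
    list(subjects = subjects, region_means = M, voxel_features = vox,
         truth = list(config = config, effect = effect, severity = severity,
                      ageing_deviation = delta, region_params = rp)),
    class = "cohort_bundle")
}

#' Generate a normative (healthy) cohort
#'
#' All subjects are healthy controls; regional GMV declines with age at
#' region-specific rates plus sex, TIV and protocol effects and noise, per
#' the generative model of [cohort_config()].
#'
#' @param config a [cohort_config()].
#' @return a `cohort_bundle`: list with `subjects` (tibble), `region_means`
#'   (subjects x regions matrix), `voxel_features` (list of subjects x voxels
#'   matrices) and `truth` (generation ground truth).
#' @export
generate_normative_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  generate_core(config)
}

#' Generate a clinical cohort (patients + controls)
#'
#' Patients receive the group effect of an [effect_spec()]: an extra GMV
#' decrement in affected parcels equivalent to `bag_shift * severity` years of
#' ageing, plus clinical variables coupled to the latent severity.
#'
#' @param config a [cohort_config()].
#' @param effect an [effect_spec()].
#' @param prop_patients fraction of subjects that are patients (default
#'   110/180, mirroring a 110 vs 70 design).
#' @return a `cohort_bundle`; `subjects$group` is a factor with levels
#'   control, patient; clinical variables are populated for patients only.
#' @export
generate_clinical_cohort <- function(config, effect, prop_patients = 110 / 180) {
  stopifnot(inherits(config, "cohort_config"), inherits(effect, "effect_spec"))
  if (length(effect$affected_regions) &&
      (min(effect$affected_regions) < 1 ||
       max(effect$affected_regions) > config$n_regions)) {
    bg_stop("affected region index out of range", class = "braingap_config_error")
  }
  n <- config$n_subjects
  n_pat <- round(n * prop_patients)
  group <- rep(c("patient", "control"), c(n_pat, n - n_pat))

  # severity and clinical noise drawn under the config seed, offset so the
  # imaging draw below (same seed) is unaffected
  sev_cl <- with_seed(config$seed + 1L, {
    sev <- c(abs(rnorm(n_pat, 1, 0.5)), numeric(n - n_pat))
    lam <- effect$latent_loadings
    sdv <- effect$clinical_noise_sd
    base <- c(headache_freq = 4, painkiller_freq = 1, midas = 14, bdi = 5,
              duration_years = 10)
    cl <- tibble::tibble(
      headache_freq = clip(base[1] + lam[1] * sev + rnorm(n, 0, sdv[1]), 0, 30),
      painkiller_freq = clip(base[2] + lam[2] * sev + rnorm(n, 0, sdv[2]), 0, 30),
      midas = clip(base[3] + lam[3] * sev + skew_noise(n, sdv[3]), 0, 270),
      bdi = clip(base[4] + lam[4] * sev + skew_noise(n, sdv[4]), 0, 63),
      duration_years = clip(base[5] + lam[5] * sev + skew_noise(n, sdv[5]), 0.5, 45))
    list(sev = sev, clinical = cl)
  })

  bundle <- generate_core(config, effect = effect, group = group,
                          severity = sev_cl$sev)
  cl <- sev_cl$clinical
  cl[group != "patient", ] <- NA_real_
  bundle$subjects[names(cl)] <- cl
  bundle$subjects$group <- factor(group, levels = c("control", "patient"))
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d subjects, %d regions x %d voxels\n",
              nrow(x$subjects), ncol(x$region_means),
              x$truth$config$voxels_per_region))
  if (!is.null(x$truth$effect)) {
    cat(sprintf("  group effect: %+g y equivalent ageing in %d regions\n",
                x$truth$effect$bag_shift,
                length(x$truth$effect$affected_regions)))
  }
  invisible(x)
}

#' Ground-truth age-equivalent GMV deviations
#'
#' Inverts the stored generation formula: for every subject and region,
#' removes the deterministic age/sex/TIV/protocol expectation and expresses
#' the residual GMV deficit in years of equivalent extra ageing. For an
#' affected region of a patient this equals
#' `bag_shift * severity + ageing_deviation + noise / slope`.
#'
#' @param bundle a `cohort_bundle`.
#' @return subjects x regions matrix of deviations (years; positive = older-
#'   appearing than chronological age).
#' @export
deviation_years <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  cfg <- bundle$truth$config
  rp <- bundle$truth$region_params
  sub <- bundle$subjects
  sidx <- match(sub$protocol, cfg$sites$protocol)
  tivfac <- (sub$tiv_ml / 1430)^cfg$tiv_coupling
  sexterm <- cfg$sex_effect * (sub$sex == "M")
  descaled <- sweep(bundle$region_means, 1, cfg$sites$shift[sidx], "-") /
    (cfg$sites$scale[sidx] * tivfac)
  # descaled = baseline - slope * (age + deviation) + sexterm
  eff_age <- sweep(-sweep(descaled - sexterm, 2, rp$baseline, "-"), 2, rp$slope, "/")
  sweep(eff_age, 1, sub$age, "-")
}

#' Analytic expected group BAG difference
#'
#' From stored ground truth only: the expected patient-minus-control
#' difference in corrected BAG. Regionally (an affected parcel) this is
#' `gain * bag_shift * mean(severity)`. Globally, a model that pools all
#' parcels weights each by its precision (inverse year-equivalent noise
#' variance), so the injected shift is diluted by the precision share of the
#' affected set.
#'
#' @param bundle a clinical `cohort_bundle`.
#' @param gain multiplicative pass-through of an input age-equivalent shift to
#'   corrected predicted age; under the additive offset correction this is the
#'   bias-model slope (use 1 for an ideal calibrated model).
#' @return list with `regional` and `global` expected differences (years).
#' @export
expected_bag_difference <- function(bundle, gain = 1) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  eff <- bundle$truth$effect
  if (is.null(eff)) return(list(regional = 0, global = 0))
  cfg <- bundle$truth$config
  rp <- bundle$truth$region_params
  pat <- bundle$subjects$group == "patient"
  mean_sev <- mean(bundle$truth$severity[pat])
  prec <- (rp$slope / cfg$noise_sd)^2
  w_aff <- sum(prec[eff$affected_regions]) / sum(prec)
  list(regional = gain * eff$bag_shift * mean_sev,
       global = gain * eff$bag_shift * mean_sev * w_aff)
}

#' Population canonical correlation implied by the generator
#'
#' For the single-latent-factor coupling of [effect_spec()], the population
#' first canonical correlation between the clinical set and the affected-
#' region age-equivalent deviations factorizes as `rho_Y * rho_X`, where each
#' factor is the maximal correlation of a linear combination of that set with
#' the latent severity. Both are closed-form: the clinical side from the
#' loadings and noise sds, the imaging side from `bag_shift`, the severity
#' moments, the ageing dispersion and the precision-pooled region noise.
#' Range truncation of clinical variables is ignored (slight overestimate).
#'
#' @param config a [cohort_config()].
#' @param effect an [effect_spec()].
#' @return list with `rho` (population canonical correlation), `rho_clinical`
#'   and `rho_imaging`.
#' @export
population_canonical_correlation <- function(config, effect) {
  fm <- folded_normal_moments(1, 0.5)
  lam <- effect$latent_loadings
  sdv <- effect$clinical_noise_sd
  use <- sdv > 0 | lam != 0
  if (any(lam != 0 & sdv == 0)) {
    rho_y <- 1
  } else {
    S <- fm$var * sum((lam[use]^2) / (sdv[use]^2))
    rho_y <- sqrt(S / (1 + S))
  }
  rp <- region_parameters(config$n_regions)
  v <- (config$noise_sd / rp$slope[effect$affected_regions])^2
  vtilde <- 1 / sum(1 / v)
  b <- effect$bag_shift
  rho_x <- b * sqrt(fm$var) /
    sqrt(b^2 * fm$var + config$ageing_dispersion^2 + vtilde)
  list(rho = rho_x * rho_y, rho_clinical = rho_y, rho_imaging = rho_x)
}

#' Write a cohort to disk as TSV + NIfTI
#'
#' Writes the subject table (TSV), one GMV volume per subject plus an integer
#' atlas and a grey-matter probability map (NIfTI, identity affine) on a small
#' 3-D lattice, and a ground-truth JSON sidecar. Voxels are laid out in the
#' array's native (column-major) linear order, region by region, so that
#' re-extraction with [extract_features()] reproduces the bundle's region
#' means exactly.
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if needed).
#' @return invisible list of file paths (`subject_table`, `atlas`, `gm_prob`,
#'   `truth`, `gmv` vector).
#' @export
emit_cohort_files <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  n <- nrow(bundle$subjects)
  if (n == 0L) bg_stop("empty bundle: no subjects to write")
  cfg <- bundle$truth$config
  n_vox_total <- cfg$n_regions * cfg$voxels_per_region
  side <- max(4L, ceiling(n_vox_total^(1 / 3)))
  dims <- c(side, side, side)
  if (prod(dims) < n_vox_total) dims[3] <- ceiling(n_vox_total / (side * side))

  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  gmv_dir <- file.path(directory, "gmv")
  dir.create(gmv_dir, showWarnings = FALSE)

  atlas <- array(0L, dims)
  atlas[seq_len(n_vox_total)] <- rep(seq_len(cfg$n_regions),
                                     each = cfg$voxels_per_region)
  gm_prob <- array(0, dims)
  gm_prob[seq_len(n_vox_total)] <- 1

  atlas_path <- file.path(directory, "atlas.nii.gz")
  prob_path <- file.path(directory, "gm_prob.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas), atlas_path)
  RNifti::writeNifti(RNifti::asNifti(gm_prob), prob_path)

  gmv_paths <- character(n)
  feat <- do.call(cbind, bundle$voxel_features)  # n x (regions*voxels), region-major
  for (s in seq_len(n)) {
    vol <- array(0, dims)
    vol[seq_len(n_vox_total)] <- feat[s, ]
    gmv_paths[s] <- file.path(gmv_dir, paste0(bundle$subjects$id[s], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol), gmv_paths[s])
  }

  tsv_path <- file.path(directory, "subjects.tsv")
  readr::write_tsv(bundle$subjects, tsv_path)

  truth_path <- file.path(directory, "truth.json")
  truth <- bundle$truth
  truth$config$sites <- as.data.frame(truth$config$sites)
  jsonlite::write_json(
    list(config = unclass(truth$config),
         effect = if (!is.null(truth$effect)) unclass(truth$effect),
         severity = truth$severity,
         ageing_deviation = truth$ageing_deviation),
    truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(subject_table = tsv_path, atlas = atlas_path,
                 gm_prob = prob_path, truth = truth_path, gmv = gmv_paths))
}
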