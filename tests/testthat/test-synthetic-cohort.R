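test_that("noiseless limit reproduces baseline - slope * age exactly", {
  cfg <- noiseless_config(n = 25, n_regions = 8)
  b <- generate_normative_cohort(cfg)
  rp <- region_parameters(8)
  expected <- outer(rep(1, 25), rp$baseline) - outer(b$subjects$age, rp$slope)
  expect_equal(unname(b$region_means), unname(expected), tolerance = 1e-12)
  # voxel features average back to the region mean exactly
  expect_equal(rowMeans(b$voxel_features[[3]]), unname(b$region_means[, 3]),
               tolerance = 1e-12)
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config(seed = 42)
  b1 <- generate_normative_cohort(cfg)
  b2 <- generate_normative_cohort(cfg)
  expect_identical(b1$region_means, b2$region_means)
  expect_identical(b1$subjects, b2$subjects)
  expect_identical(b1$voxel_features, b2$voxel_features)
  b3 <- generate_normative_cohort(tiny_config(seed = 43))
  expect_false(identical(b1$region_means, b3$region_means))
})

test_that("age-related decline yields negative age correlations (direct oracle)", {
  cfg <- cohort_config(500, n_regions = 30, voxels_per_region = 2,
                       noise_sd = 0.001, seed = 9)
  b <- generate_normative_cohort(cfg)
  # brute-force correlation of age with every region mean
  cors <- vapply(seq_len(30), function(r) cor(b$subjects$age, b$region_means[, r]),
                 numeric(1))
  expect_true(all(cors < 0))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(5), "n_subjects", class = "braingap_config_error")
  expect_error(cohort_config(20, age_range = c(50, 30)), "age_range",
               class = "braingap_config_error")
  expect_error(cohort_config(20, noise_sd = -1), "noise_sd",
               class = "braingap_config_error")
  expect_error(cohort_config(20, voxels_per_region = 0), "voxels_per_region",
               class = "braingap_config_error")
})

test_that("clinical cohort: out-of-range affected region errors", {
  cfg <- tiny_config(n_regions = 10)
  expect_error(generate_clinical_cohort(cfg, effect_spec(c(5, 11))),
               "out of range", class = "braingap_config_error")
})

test_that("null effect leaves patient and control regional distributions equal", {
  cfg <- tiny_config(n = 160, n_regions = 20, seed = 31)
  cl <- generate_clinical_cohort(cfg, effect_spec(1:5, bag_shift = 0))
  pat <- cl$subjects$group == "patient"
  p <- vapply(1:5, function(r) {
    stats::t.test(cl$region_means[pat, r], cl$region_means[!pat, r])$p.value
  }, numeric(1))
  expect_true(all(p > 1e-3))
})

test_that("noiseless loadings make clinical variables rank-correlated with severity", {
  cfg <- noiseless_config(n = 60)
  eff <- effect_spec(1:3, bag_shift = 2,
                     latent_loadings = c(headache_freq = 1, painkiller_freq = 1,
                                         midas = 1, bdi = 0, duration_years = 0),
                     clinical_noise_sd = c(headache_freq = 0, painkiller_freq = 0,
                                           midas = 0, bdi = 0, duration_years = 0))
  cl <- generate_clinical_cohort(cfg, eff)
  pat <- cl$subjects$group == "patient"
  sev <- cl$truth$severity[pat]
  expect_equal(cor(cl$subjects$headache_freq[pat], sev, method = "spearman"), 1)
  expect_equal(cor(cl$subjects$painkiller_freq[pat], sev, method = "spearman"), 1)
})

test_that("injected decrement equals slope * bag_shift * severity exactly (paired runs)", {
  cfg <- tiny_config(n = 180, n_regions = 30, seed = 77)
  aff <- c(3, 10, 22)
  eff <- effect_spec(aff, bag_shift = 4)
  null_eff <- effect_spec(aff, bag_shift = 0)
  cl1 <- generate_clinical_cohort(cfg, eff)
  cl0 <- generate_clinical_cohort(cfg, null_eff)
  # identical seeds: the only difference is the deterministic decrement
  diff <- cl0$region_means - cl1$region_means
  rp <- region_parameters(30)
  sidx <- match(cl1$subjects$protocol, cfg$sites$protocol)
  scale_fac <- cfg$sites$scale[sidx] * (cl1$subjects$tiv_ml / 1430)^cfg$tiv_coupling
  for (r in aff) {
    expect_equal(diff[, r], scale_fac * rp$slope[r] * 4 * cl1$truth$severity,
                 tolerance = 1e-10)
  }
  expect_equal(max(abs(diff[, -aff])), 0)
  # mean decrement in affected regions matches the analytic expectation
  pat <- cl1$subjects$group == "patient"
  mean_dec <- mean(diff[pat, aff])
  # expectation separates over regions and subjects
  analytic <- 4 * mean(rp$slope[aff]) *
    mean(scale_fac[pat] * cl1$truth$severity[pat])
  expect_equal(mean_dec, analytic, tolerance = 1e-10)
})

test_that("deviation_years inverts the generation formula", {
  cfg <- cohort_config(40, n_regions = 10, voxels_per_region = 2,
                       noise_sd = 0, voxel_noise_sd = 0, ageing_dispersion = 0,
                       seed = 3)
  eff <- effect_spec(c(2, 7), bag_shift = 5)
  cl <- generate_clinical_cohort(cfg, eff)
  dev <- deviation_years(cl)
  pat <- cl$subjects$group == "patient"
  expect_equal(dev[, 2], 5 * cl$truth$severity, tolerance = 1e-8)
  expect_equal(max(abs(dev[, -c(2, 7)])), 0, tolerance = 1e-8)
  expect_true(all(abs(dev[!pat, ]) < 1e-8))
})

test_that("expected BAG difference is analytic from stored truth", {
  cfg <- tiny_config(n = 120, n_regions = 20, seed = 5)
  eff <- effect_spec(1:4, bag_shift = 4)
  cl <- generate_clinical_cohort(cfg, eff)
  out <- expected_bag_difference(cl, gain = 0.9)
  pat <- cl$subjects$group == "patient"
  ms <- mean(cl$truth$severity[pat])
  expect_equal(out$regional, 0.9 * 4 * ms)
  rp <- region_parameters(20)
  prec <- (rp$slope / cfg$noise_sd)^2
  expect_equal(out$global, 0.9 * 4 * ms * sum(prec[1:4]) / sum(prec))
})

test_that("population canonical correlation formula matches a large-sample estimate", {
  cfg <- cohort_config(3000, seed = 21)
  # few imaging columns keep the O(q/n) sample-CCA inflation negligible
  eff <- effect_spec(default_affected_regions(cfg, 10), bag_shift = 8)
  pop <- population_canonical_correlation(cfg, eff)
  cl <- generate_clinical_cohort(cfg, eff, prop_patients = 1800 / 3000)
  pat <- cl$subjects$group == "patient"
  Y <- as.matrix(cl$subjects[pat, c("headache_freq", "painkiller_freq", "midas",
                                    "bdi", "duration_years")])
  X <- deviation_years(cl)[pat, eff$affected_regions]
  r1 <- cancor(residualize(Y), residualize(X))$cor[1]
  # sample canonical r at n=1800 vs analytic population value
  expect_equal(r1, pop$rho, tolerance = 0.05)
  expect_true(pop$rho_clinical < 1 && pop$rho_imaging < 1)
})
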