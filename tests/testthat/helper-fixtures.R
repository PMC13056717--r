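# small-cohort configuration used across unit tests
tiny_config <- function(n = 40, n_regions = 12, voxels = 4, seed = 1, ...) {
  cohort_config(n_subjects = n, n_regions = n_regions,
                voxels_per_region = voxels, seed = seed, ...)
}

# effects-off configuration: pure baseline - slope * age signal
noiseless_config <- function(n = 40, n_regions = 12, seed = 1) {
  cohort_config(n_subjects = n, n_regions = n_regions, voxels_per_region = 4,
                sites = tibble::tibble(protocol = "P1", prob = 1, shift = 0, scale = 1),
                sex_effect = 0, tiv_coupling = 0, noise_sd = 0,
                voxel_noise_sd = 0, ageing_dispersion = 0, seed = seed)
}

# nested foci database: sub-domains nest within the five domains
make_foci_db <- function(n = 300, seed = 7, space = "MNI", lim = 19) {
  withr::with_seed(seed, {
    domains <- c("action", "cognition", "emotion", "interoception", "perception")
    subs <- paste0(rep(domains, each = 3), ".", rep(1:3, 5))
    sub <- sample(subs, n, replace = TRUE)
    db <- tibble::tibble(
      x_mm = runif(n, 0, lim), y_mm = runif(n, 0, lim), z_mm = runif(n, 0, lim),
      domain = sub("\\..*", "", sub), subdomain = sub,
      source = sprintf("study%02d", sample(20, n, TRUE)), space = space)
    structure(db, space = space, class = c("foci_database", class(db)))
  })
}

write_foci_tsv <- function(db, path = withr::local_tempfile(fileext = ".tsv",
                                                            .local_envir = parent.frame())) {
  readr::write_tsv(db, path)
  path
}
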