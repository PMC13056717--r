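test_that("sums of squares match the hand-worked two-group example", {
  d <- tibble::tibble(bag = c(1, 2, 3, 3, 4, 5),
                      group = rep(c("A", "B"), each = 3))
  a <- ancova_compare(d, covariates = character(0))
  # SS_between = 6, SS_within = 4 -> eta_p^2 = 0.6, F = 6/(4/4) = 6
  expect_equal(a$eta_p2, 0.6, tolerance = 1e-12)
  expect_equal(a$statistic, 6, tolerance = 1e-12)
  expect_equal(a$estimate, 2)
  # eta_p^2 == F*df1 / (F*df1 + df2) identity
  expect_equal(a$eta_p2,
               a$statistic * a$df[1] / (a$statistic * a$df[1] + a$df[2]),
               tolerance = 1e-10)
  expect_true(a$conf_low <= a$estimate && a$estimate <= a$conf_high)
})

test_that("perfectly balanced covariates leave the raw difference unadjusted", {
  withr::with_seed(1, {
    cov_block <- tibble::tibble(age = rep(c(30, 40, 50, 60), 2),
                                sex = rep(c("F", "M", "F", "M"), 2))
    d <- dplyr::bind_cols(cov_block,
                          tibble::tibble(group = rep(c("a", "b"), each = 4),
                                         bag = c(rnorm(4), rnorm(4) + 3)))
    a <- ancova_compare(d, covariates = c("age", "sex"))
    raw <- mean(d$bag[d$group == "b"]) - mean(d$bag[d$group == "a"])
    expect_equal(a$estimate, raw, tolerance = 1e-10)
  })
})

test_that("shuffled labels within one sample give a null result", {
  withr::with_seed(2, {
    n <- 200
    d <- tibble::tibble(bag = rnorm(n), age = runif(n, 20, 90),
                        group = sample(rep(c("x", "y"), n / 2)))
    a <- ancova_compare(d, covariates = c("age", "age2"))
    expect_lt(abs(a$estimate), 0.5)
    expect_lt(a$eta_p2, 0.05)
  })
})

test_that("ANCOVA validates its design", {
  d <- tibble::tibble(bag = rnorm(10), group = rep("only", 10))
  expect_error(ancova_compare(d, covariates = character(0)), "two groups")
  d2 <- tibble::tibble(bag = rnorm(10), group = rep(c("a", "b"), 5),
                       age = 1:10, age_copy = 1:10)
  expect_error(ancova_compare(d2, covariates = c("age", "age_copy")),
               "collinear", class = "braingap_rank_error")
})

test_that("three-group comparison returns omnibus F plus pairwise contrasts", {
  withr::with_seed(3, {
    d <- tibble::tibble(bag = c(rnorm(30), rnorm(30) + 1, rnorm(30) + 3),
                        group = rep(c("HC", "EM", "CM"), each = 30),
                        age = runif(90, 20, 60))
    d$group <- factor(d$group, levels = c("HC", "EM", "CM"))
    a <- ancova_compare(d, covariates = "age")
    expect_equal(a$df[1], 2)
    expect_equal(nrow(a$contrasts), 3)
    cm_hc <- a$contrasts$estimate[a$contrasts$contrast == "CM - HC"]
    expect_gt(cm_hc, 1.5)
    expect_lt(a$p_value, 0.001)
  })
})

test_that("BH selection matches the hand-worked step-up example", {
  sel <- fdr_select(c(0.001, 0.01, 0.02, 0.04, 0.9), q = 0.05)
  expect_equal(sum(sel$significant), 4)   # 0.04 <= (4/5)*0.05
  expect_true(all(sel$p_adj >= sel$p))
  expect_equal(fdr_select(1 - 1e-12)$p_adj, 1 - 1e-12)  # m = 1 identity
  expect_equal(sum(fdr_select(rep(1, 8))$significant), 0)
  expect_error(fdr_select(numeric(0)), "empty")
  expect_error(fdr_select(c(0.5, 1.2)), "0, 1")
})

test_that("regional ANCOVA agrees with per-region ancova_compare", {
  withr::with_seed(4, {
    n <- 80
    d <- tibble::tibble(group = factor(rep(c("control", "patient"), each = n / 2)),
                        age = runif(n, 20, 80), sex = sample(c("F", "M"), n, TRUE),
                        tiv_ml = rnorm(n, 1430, 100),
                        protocol = sample(c("A", "B"), n, TRUE))
    bag <- matrix(rnorm(n * 6), n, dimnames = list(NULL, sprintf("R%03d", 1:6)))
    bag[d$group == "patient", 2] <- bag[d$group == "patient", 2] + 2
    reg <- regional_ancova(bag, d)
    for (r in c(1, 2, 5)) {
      a <- ancova_compare(dplyr::mutate(d, bag = bag[, r]))
      expect_equal(reg$estimate[r], a$estimate, tolerance = 1e-10)
      expect_equal(reg$statistic[r], a$statistic, tolerance = 1e-10)
      expect_equal(reg$p_value[r], a$p_value, tolerance = 1e-10)
      expect_equal(reg$eta_p2[r], a$eta_p2, tolerance = 1e-10)
    }
    expect_true(reg$significant[2])
  })
})

test_that("stratified comparison: identical strata give identical results; one stratum reduces", {
  withr::with_seed(5, {
    n <- 60
    base <- tibble::tibble(group = rep(c("control", "patient"), each = n / 2),
                           age = runif(n, 20, 80), sex = sample(c("F", "M"), n, TRUE),
                           tiv_ml = rnorm(n, 1430, 100),
                           bag = rnorm(n) + rep(c(0, 2), each = n / 2))
    two <- dplyr::bind_rows(dplyr::mutate(base, protocol = "P1"),
                            dplyr::mutate(base, protocol = "P2"))
    out <- stratified_compare(two)
    expect_equal(nrow(out), 2)
    expect_equal(out$estimate[1], out$estimate[2], tolerance = 1e-10)
    expect_equal(out$p_value[1], out$p_value[2], tolerance = 1e-10)
    one <- dplyr::mutate(base, protocol = "P1")
    o1 <- stratified_compare(one)
    plain <- ancova_compare(one, covariates = c("age", "age2", "sex", "tiv_ml"))
    expect_equal(o1$estimate, plain$estimate, tolerance = 1e-12)
    expect_equal(o1$statistic, plain$statistic, tolerance = 1e-12)
  })
})

test_that("strata missing a group are skipped with a warning", {
  withr::with_seed(6, {
    d <- tibble::tibble(group = c(rep(c("control", "patient"), 10), rep("control", 8)),
                        age = runif(28, 20, 80),
                        bag = rnorm(28),
                        protocol = c(rep("P1", 20), rep("P2", 8)))
    expect_warning(out <- stratified_compare(d, covariates = c("age", "protocol")),
                   "P2")
    expect_equal(out$stratum, "P1")
  })
})
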