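test_that("residualization is orthogonal, idempotent, and centring-only without confounds", {
  withr::with_seed(1, {
    n <- 60
    c1 <- rnorm(n)
    y <- 2 * c1 + rnorm(n)
    Z <- cbind(c1)
    r <- residualize(cbind(y), Z)
    expect_lt(abs(cor(r[, 1], c1)), 1e-10)
    expect_equal(residualize(r, Z), r, tolerance = 1e-12)
    # column orthogonal to the (centred) confound only loses its mean
    c1c <- c1 - mean(c1)
    y2 <- rnorm(n)
    y2 <- y2 - mean(y2)
    y2 <- y2 - c1c * sum(y2 * c1c) / sum(c1c^2)
    y3 <- y2 + 7
    r2 <- residualize(cbind(y3), cbind(c1c))
    expect_equal(r2[, 1], y2, tolerance = 1e-10)
    expect_error(residualize(cbind(y), cbind(c1, c1)), "rank",
                 class = "braingap_rank_error")
  })
})

test_that("PCA reduction picks the minimal component count for the variance target", {
  withr::with_seed(2, {
    X2 <- cbind(rnorm(200), rnorm(200))      # two independent unit-variance columns
    p2 <- pca_reduce(X2, 0.5)
    expect_equal(p2$k, 1L)                   # first PC explains >= 50% by symmetry
    v <- rnorm(50)
    rank1 <- outer(v, c(1, 2, 3))
    p1 <- pca_reduce(rank1, 0.5)
    expect_equal(p1$k, 1L)
    expect_equal(p1$cumulative, 1, tolerance = 1e-12)
    # eigen-decomposition oracle on a random 80 x 66 matrix
    X <- matrix(rnorm(80 * 66), 80)
    pr <- pca_reduce(X, 0.5)
    ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
    cum <- cumsum(ev) / sum(ev)
    k_oracle <- which(cum >= 0.5)[1]
    expect_equal(pr$k, k_oracle)
    expect_gte(cum[pr$k], 0.5)
    if (pr$k > 1) expect_lt(cum[pr$k - 1], 0.5)
    expect_error(pca_reduce(matrix(1, 10, 3)), "degenerate")
  })
})

test_that("a copied set gives r = 1 with the smallest attainable p", {
  withr::with_seed(3, {
    Y <- matrix(rnorm(40 * 2), 40)
    f <- permcca(Y, Y, nperm = 199, seed = 4)
    expect_equal(f$r[1], 1, tolerance = 1e-8)
    expect_equal(f$p[1], 1 / 200)
  })
})

test_that("exhaustive n = 6 permutation p matches a brute-force enumeration oracle", {
  withr::with_seed(4, {
    y <- rnorm(6); x <- y + rnorm(6, 0, 0.5)
    f <- permcca(cbind(y), cbind(x), nperm = 1000, seed = 1)
    expect_true(f$exhaustive)
    expect_equal(f$nperm, 720)
    # oracle: squared correlation over all 720 row orders
    perms <- braingap:::all_permutations(6)
    yc <- y - mean(y); xc <- x - mean(x)
    r2_obs <- cor(y, x)^2
    r2_all <- apply(perms, 1, function(p) cor(yc[p], xc)^2)
    expect_equal(f$p[1], mean(r2_all >= r2_obs - 1e-12))
  })
})

test_that("CCA is invariant to invertible affine transforms of either set", {
  withr::with_seed(5, {
    Y <- matrix(rnorm(50 * 3), 50)
    X <- matrix(rnorm(50 * 4), 50)
    X[, 1] <- X[, 1] + Y[, 1]
    f0 <- permcca(Y, X, nperm = 99, seed = 1)
    A <- matrix(rnorm(9), 3); while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    B <- matrix(rnorm(16), 4); while (abs(det(B)) < 0.1) B <- matrix(rnorm(16), 4)
    f1 <- permcca(sweep(Y %*% A, 2, c(1, -2, 3), "+"), X %*% B,
                  nperm = 99, seed = 1)
    expect_equal(f0$r, f1$r, tolerance = 1e-8)
  })
})

test_that("loading inference: self-variate loads at 1; null variables stay null; signs flip", {
  withr::with_seed(6, {
    n <- 80
    latent <- rnorm(n)
    Y <- cbind(v1 = latent + rnorm(n, 0, 0.1), v2 = rnorm(n), v3 = rnorm(n))
    X <- cbind(latent + rnorm(n, 0, 0.1), rnorm(n))
    f <- permcca(Y, X, nperm = 199, seed = 2)
    li <- loading_inference(f, nperm = 199, seed = 3)
    expect_gt(li$loading[li$variable == "v1"], 0.95)
    expect_true(li$significant[li$variable == "v1"])
    expect_false(li$significant[li$variable == "v2"])
    # a variable identical to the variate has loading 1
    expect_equal(max(abs(cor(f$y_scores[, 1], f$y_scores[, 1]))), 1)
    # sign equivariance of loadings under variate sign flip
    l_pos <- cor(residualize(Y), f$y_scores[, 1])
    l_neg <- cor(residualize(Y), -f$y_scores[, 1])
    expect_equal(l_neg, -l_pos)
  })
})

test_that("sign convention puts the dominant clinical loading positive", {
  withr::with_seed(7, {
    n <- 70
    latent <- rnorm(n)
    Y <- cbind(a = -latent + rnorm(n, 0, 0.2), b = rnorm(n))
    X <- cbind(latent + rnorm(n, 0, 0.2))
    f <- permcca(Y, X, nperm = 99, seed = 1)
    expect_gt(f$y_loadings[which.max(abs(f$y_loadings[, 1])), 1], 0)
  })
})

test_that("bootstrap: planted association excludes zero; nboot = 1 degenerates to a point", {
  withr::with_seed(8, {
    n <- 200
    latent <- rnorm(n)
    Y <- cbind(latent + rnorm(n, 0, 0.5), rnorm(n))
    X <- cbind(latent + rnorm(n, 0, 0.5), rnorm(n))
    f <- permcca(Y, X, nperm = 99, seed = 1)
    b <- bootstrap_stability(f, nboot = 200, seed = 2)
    expect_gt(b$r["lower"], 0)   # population r ~ 0.8
    b1 <- bootstrap_stability(f, nboot = 1, seed = 3)
    expect_equal(unname(b1$r["lower"]), unname(b1$r["upper"]))
    expect_error(bootstrap_stability(permcca(Y[1:15, ], X[1:15, ], nperm = 99)),
                 "at least 20")
  })
})

test_that("null-data bootstrap intervals are wide and straddle zero for loadings", {
  withr::with_seed(9, {
    Y <- matrix(rnorm(80 * 3), 80)
    X <- matrix(rnorm(80 * 3), 80)
    f <- permcca(Y, X, nperm = 99, seed = 1)
    b <- bootstrap_stability(f, nboot = 300, seed = 2)
    straddle <- b$loadings$lower < 0 & b$loadings$upper > 0
    expect_gte(sum(straddle), 2)
  })
})

test_that("region contributions equal a brute-force column-wise correlation", {
  withr::with_seed(10, {
    n <- 80
    latent <- rnorm(n)
    Y <- cbind(latent + rnorm(n, 0, 0.3), rnorm(n))
    X <- cbind(latent + rnorm(n, 0, 0.3), rnorm(n))
    f <- permcca(Y, X, nperm = 99, seed = 1)
    bag <- cbind(r1 = f$y_scores[, 1],           # identical to the variate
                 r2 = rnorm(n),                  # pure noise
                 r3 = latent + rnorm(n))
    rc <- region_contributions(f, bag)
    expect_equal(rc$r[1], 1, tolerance = 1e-10)
    expect_lt(abs(rc$r[2]), 0.35)
    brute <- vapply(1:3, function(j) cor(bag[, j], f$y_scores[, 1]), numeric(1))
    expect_equal(rc$r, brute, tolerance = 1e-12)
    # constant region flagged
    rc2 <- region_contributions(f, cbind(const = rep(1, n)))
    expect_true(rc2$constant[1])
    expect_true(is.na(rc2$r[1]))
  })
})

test_that("permutation p-values are valid under the null (mini calibration)", {
  withr::with_seed(11, {
    p1 <- vapply(1:60, function(i) {
      Y <- matrix(rnorm(30 * 2), 30)
      X <- matrix(rnorm(30 * 2), 30)
      permcca(Y, X, nperm = 99, seed = i)$p[1]
    }, numeric(1))
    # super-uniformity: rejection at 0.05 should not exceed ~ nominal
    expect_lte(mean(p1 <= 0.05), 0.15)
    expect_gt(mean(p1), 0.3)
  })
})
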