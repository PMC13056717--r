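#' ComBat location-scale batch harmonization
#'
#' Removes additive and multiplicative batch (acquisition-protocol) effects
#' from a samples x features matrix while preserving the variance associated
#' with biological covariates, using the parametric empirical-Bayes
#' location-scale model of Johnson et al. Batch effect estimates are shrunk
#' across features toward a common prior (`eb = TRUE`); with `eb = FALSE`
#' the per-feature estimates are used directly (plain per-batch
#' standardization), which is also what a single-feature input reduces to.
#'
#' @param data numeric vector (one feature, e.g. global BAG) or samples x
#'   features matrix / data frame (e.g. regional BAG or features).
#' @param batch batch labels, one per sample; every batch needs >= 2 samples.
#' @param design optional samples x covariates model matrix (without
#'   intercept) of biological effects to preserve (e.g. group, age, sex,
#'   TIV dummies).
#' @param eb use empirical-Bayes shrinkage across features (needs >= 2
#'   features; otherwise estimates are used unshrunk).
#' @param tol convergence tolerance of the EB fixed-point iteration.
#' @return harmonized data with the input's shape.
#' @export
combat_harmonize <- function(data, batch, design = NULL, eb = TRUE, tol = 1e-8) {
  vec_in <- is.null(dim(data))
  X <- as.matrix(data)          # n samples x p features
  n <- nrow(X); p <- ncol(X)
  batch <- factor(batch)
  if (length(batch) != n) bg_stop("`batch` length must match sample count")
  nb <- table(batch)
  if (any(nb < 2L)) {
    bg_stop(sprintf("batch with fewer than 2 samples: %s",
                    paste(names(nb)[nb < 2L], collapse = ", ")))
  }
  if (nlevels(batch) == 1L) {
    rlang::inform("single batch: nothing to harmonize")
    return(data)
  }
  B <- model.matrix(~ 0 + batch)              # cell-means batch design
  D <- if (is.null(design)) NULL else as.matrix(design)
  M <- cbind(B, D)
  qm <- qr(M)
  if (qm$rank < ncol(M)) {
    bg_stop("design confounded with batch", class = "braingap_rank_error")
  }
  beta <- qr.coef(qm, X)                      # (nbatch + q) x p
  gamma_hat <- beta[seq_len(nlevels(batch)), , drop = FALSE]
  beta_cov <- beta[-seq_len(nlevels(batch)), , drop = FALSE]
  grand <- as.numeric(crossprod(nb / n, gamma_hat))      # weighted grand mean
  stand_mean <- matrix(grand, n, p, byrow = TRUE)
  if (!is.null(D)) stand_mean <- stand_mean + D %*% beta_cov
  resid <- X - B %*% gamma_hat - (if (is.null(D)) 0 else D %*% beta_cov)
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled <= 0)) bg_stop("zero-variance feature; cannot standardize")
  Z <- (X - stand_mean) / matrix(sqrt(var_pooled), n, p, byrow = TRUE)

  g_hat <- d2_hat <- matrix(NA_real_, nlevels(batch), p)
  for (b in seq_len(nlevels(batch))) {
    zb <- Z[batch == levels(batch)[b], , drop = FALSE]
    g_hat[b, ] <- colMeans(zb)
    d2_hat[b, ] <- apply(zb, 2, var)
  }

  use_eb <- eb && p >= 2L
  if (use_eb) {
    g_star <- d2_star <- matrix(NA_real_, nlevels(batch), p)
    for (b in seq_len(nlevels(batch))) {
      gb <- g_hat[b, ]; d2b <- d2_hat[b, ]
      g_bar <- mean(gb); tau2 <- var(gb)
      m <- mean(d2b); s2 <- var(d2b)
      # inverse-gamma prior hyperparameters by moment matching
      lambda <- (2 * s2 + m^2) / s2
      theta <- (m * s2 + m^3) / s2
      nb_b <- sum(batch == levels(batch)[b])
      g <- gb; d2 <- d2b
      zb <- Z[batch == levels(batch)[b], , drop = FALSE]
      repeat {
        g_new <- (nb_b * tau2 * gb + d2 * g_bar) / (nb_b * tau2 + d2)
        ss <- colSums((zb - matrix(g_new, nb_b, p, byrow = TRUE))^2)
        d2_new <- (theta + 0.5 * ss) / (nb_b / 2 + lambda - 1)
        if (max(abs(g_new - g), abs(d2_new - d2)) < tol) { g <- g_new; d2 <- d2_new; break }
        g <- g_new; d2 <- d2_new
      }
      g_star[b, ] <- g; d2_star[b, ] <- d2
    }
  } else {
    g_star <- g_hat; d2_star <- d2_hat
  }

  Zadj <- Z
  for (b in seq_len(nlevels(batch))) {
    ii <- batch == levels(batch)[b]
    Zadj[ii, ] <- (Z[ii, , drop = FALSE] -
                     matrix(g_star[b, ], sum(ii), p, byrow = TRUE)) /
      matrix(sqrt(d2_star[b, ]), sum(ii), p, byrow = TRUE)
  }
  out <- Zadj * matrix(sqrt(var_pooled), n, p, byrow = TRUE) + stand_mean
  dimnames(out) <- dimnames(X)
  if (vec_in) as.numeric(out) else out
}
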