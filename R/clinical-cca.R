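#' Residualize a data matrix on confounds
#'
#' Replaces every column by its OLS residual on the confound matrix (an
#' intercept is always included), so residuals are exactly orthogonal to the
#' confounds and mean-centred. With `confounds = NULL` columns are centred
#' only.
#'
#' @param data numeric matrix / data frame (samples x variables).
#' @param confounds numeric matrix of confounds (samples x q), or `NULL`.
#' @return residual matrix, same shape as `data`.
#' @export
residualize <- function(data, confounds = NULL) {
  X <- as.matrix(data)
  if (anyNA(X)) bg_stop("data contain missing values; use complete cases")
  if (is.null(confounds)) return(scale(X, scale = FALSE)[, , drop = FALSE])
  Z <- cbind(1, as.matrix(confounds))
  if (qr(Z)$rank < ncol(Z)) {
    bg_stop("rank-deficient confound matrix", class = "braingap_rank_error")
  }
  out <- ols_residuals(X, Z)
  dimnames(out) <- dimnames(X)
  out
}

#' PCA reduction to a target explained variance
#'
#' Principal components of the centred matrix; keeps the smallest number of
#' leading components whose cumulative explained variance reaches the target
#' (default 50%, the usual choice when reducing many collinear regional BAG
#' columns before CCA).
#'
#' @param data samples x variables matrix (>= 2 variables).
#' @param variance_target fraction of variance to retain, in (0, 1].
#' @return object of class `pca_reduction`: `scores` (n x k), `rotation`,
#'   `center`, `explained` (per-component fractions), `k`.
#' @export
pca_reduce <- function(data, variance_target = 0.5) {
  X <- as.matrix(data)
  if (ncol(X) < 2L) bg_stop("PCA reduction needs at least 2 columns")
  if (variance_target <= 0 || variance_target > 1) {
    bg_stop("`variance_target` must be in (0, 1]")
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (sum(ev) <= 0) bg_stop("degenerate (zero-variance) matrix")
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, explained = frac, k = k,
                 cumulative = cumsum(frac)[k]),
            class = "pca_reduction")
}

#' Project new data onto a fixed PCA basis
#' @param pca a [pca_reduce()] result.
#' @param newdata samples x variables matrix on the original columns.
#' @return samples x k score matrix.
#' @export
project_pca <- function(pca, newdata) {
  sweep(as.matrix(newdata), 2, pca$center) %*% pca$rotation
}

# all permutations of 1..n (used for exhaustive inference at tiny n)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[pos] <- n
      perm[-pos] <- sub[r, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

# Wilks-lambda step-down statistics: stat[m] = -sum_{j>=m} log(1 - r_j^2)
wilks_stats <- function(r) {
  rev(cumsum(rev(-log1p(-pmin(r^2, 1 - 1e-12)))))
}

#' Permutation-based canonical correlation analysis
#'
#' Canonical correlation between two variable sets after confound removal,
#' with non-parametric inference: both sets are residualized on their
#' respective confounds, the imaging set is optionally PCA-reduced to a
#' target explained variance, and each canonical mode is tested by permuting
#' subject rows of the residualized clinical set. Mode m uses the step-down
#' Wilks statistic `-sum_{j >= m} log(1 - r_j^2)`, so later modes are tested
#' on the variance left after earlier ones; permutation ties count as
#' exceedances and p-values use the +1 convention
#' `(1 + #{perm >= obs}) / (1 + nperm)`. When `n!` does not exceed `nperm`
#' the test enumerates all row orders exhaustively instead (p is then the
#' exact fraction of orders, identity included). Mode signs are fixed so the
#' largest-magnitude clinical loading is positive.
#'
#' @param y clinical set (samples x variables), complete cases.
#' @param x imaging set (samples x variables), e.g. regional BAG.
#' @param z_y,z_x confound matrices for each set (`NULL` = centre only);
#'   typically age + sex for the clinical set and age, age squared, sex,
#'   TIV and protocol for the imaging set.
#' @param nperm number of permutations (>= 99).
#' @param seed RNG seed for the permutations.
#' @param variance_target if non-`NULL`, PCA-reduce the residualized `x` to
#'   this explained-variance fraction before CCA.
#' @return object of class `permcca`: canonical correlations `r`, monotone
#'   step-down permutation `p`, subject `y_scores`/`x_scores`, `y_loadings`,
#'   `x_loadings`, the `pca` reduction (if any), and the inputs (for
#'   [bootstrap_stability()] and [loading_inference()]).
#' @export
permcca <- function(y, x, z_y = NULL, z_x = NULL, nperm = 1000, seed = 1L,
                    variance_target = NULL) {
  Y <- as.matrix(y); X <- as.matrix(x)
  if (nrow(Y) != nrow(X)) bg_stop("y and x must have the same rows")
  if (anyNA(Y) || anyNA(X)) bg_stop("missing values: supply complete cases only")
  if (nperm < 99) bg_stop("nperm must be >= 99")
  n <- nrow(Y)
  Yr <- residualize(Y, z_y)
  Xr <- residualize(X, z_x)
  pca <- NULL
  Xu <- Xr
  if (!is.null(variance_target) && ncol(Xr) >= 2L) {
    pca <- pca_reduce(Xr, variance_target)
    Xu <- pca$scores
  }
  kx <- qr(Xu)$rank; ky <- qr(Yr)$rank
  if (n <= kx + ky + 1L) bg_stop("too few subjects for the requested number of modes")

  cc <- cancor(Yr, Xu)
  r <- cc$cor
  m <- length(r)
  obs <- wilks_stats(r)

  n_orders <- factorial(n)
  exhaustive <- is.finite(n_orders) && n_orders <= nperm
  if (exhaustive) {
    perms <- all_permutations(n)
    exceed <- matrix(0, nrow(perms), m)
    for (i in seq_len(nrow(perms))) {
      rp <- cancor(Yr[perms[i, ], , drop = FALSE], Xu)$cor
      exceed[i, ] <- wilks_stats(rp) >= obs - 1e-12
    }
    p <- colMeans(exceed)
    nperm_eff <- nrow(perms)
  } else {
    counts <- numeric(m)
    with_seed(seed, {
      for (i in seq_len(nperm)) {
        rp <- cancor(Yr[sample.int(n), , drop = FALSE], Xu)$cor
        counts <- counts + (wilks_stats(rp) >= obs - 1e-12)
      }
    })
    p <- (1 + counts) / (1 + nperm)
    nperm_eff <- nperm
  }
  p <- cummax(p)   # step-down monotonicity

  # cancor(Yr, Xu): xcoef/xcenter belong to the first argument (clinical set)
  y_scores <- scale(Yr, center = cc$xcenter, scale = FALSE) %*% cc$xcoef[, seq_len(m), drop = FALSE]
  x_scores <- scale(Xu, center = cc$ycenter, scale = FALSE) %*% cc$ycoef[, seq_len(m), drop = FALSE]
  y_load <- cor(Yr, y_scores)
  # sign convention per mode: dominant clinical loading positive
  for (j in seq_len(m)) {
    s <- sign(y_load[which.max(abs(y_load[, j])), j])
    if (s < 0) {
      y_scores[, j] <- -y_scores[, j]
      x_scores[, j] <- -x_scores[, j]
    }
  }
  y_load <- cor(Yr, y_scores)
  x_load <- cor(Xu, x_scores)
  colnames(y_scores) <- colnames(x_scores) <- paste0("mode", seq_len(m))

  structure(list(r = r, p = as.numeric(p), n = n, nperm = nperm_eff,
                 exhaustive = exhaustive,
                 y_scores = y_scores, x_scores = x_scores,
                 y_loadings = y_load, x_loadings = x_load,
                 pca = pca,
                 inputs = list(y = Y, x = X, z_y = z_y, z_x = z_x,
                               variance_target = variance_target, seed = seed)),
            class = "permcca")
}

#' @export
print.permcca <- function(x, ...) {
  cat(sprintf("<permcca> n = %d, %s permutations%s\n", x$n, format(x$nperm),
              if (x$exhaustive) " (exhaustive)" else ""))
  for (j in seq_along(x$r)) {
    cat(sprintf("  mode %d: r = %.3f, p = %.4g\n", j, x$r[j], x$p[j]))
  }
  invisible(x)
}

#' FWE-corrected inference on clinical canonical loadings
#'
#' Loadings are correlations of each clinical variable with the mode-1
#' clinical canonical variate. Family-wise error control across the
#' variables uses the max-statistic permutation distribution: rows of the
#' residualized clinical set are permuted against the observed canonical
#' variate (breaking each variable's alignment with the identified mode
#' while keeping the variate fixed), the maximum absolute correlation across
#' variables is recorded per permutation, and each observed loading is
#' compared against that distribution.
#'
#' @param fit a [permcca()] result (mode 1 should be significant before
#'   interpreting loadings).
#' @param nperm permutations for the max-statistic null.
#' @param seed RNG seed.
#' @param alpha FWE level for the significance flag.
#' @return tibble with `variable`, `loading`, `p_fwe`, `significant`;
#'   zero-variance variables get `NA` loadings and a flag.
#' @export
loading_inference <- function(fit, nperm = 1000, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(fit, "permcca"))
  Yr <- residualize(fit$inputs$y, fit$inputs$z_y)
  degenerate <- apply(Yr, 2, sd) == 0
  obs <- fit$y_loadings[, 1]
  obs[degenerate] <- NA_real_
  n <- nrow(Yr)
  v_obs <- fit$y_scores[, 1]
  maxstat <- numeric(nperm)
  with_seed(seed, {
    for (i in seq_len(nperm)) {
      Yp <- Yr[sample.int(n), , drop = FALSE]
      maxstat[i] <- max(abs(cor(Yp[, !degenerate, drop = FALSE], v_obs)))
    }
  })
  p_fwe <- vapply(obs, function(l) {
    if (is.na(l)) return(NA_real_)
    (1 + sum(maxstat >= abs(l) - 1e-12)) / (1 + nperm)
  }, numeric(1))
  tibble::tibble(
    variable = colnames(Yr) %||% paste0("y", seq_along(obs)),
    loading = as.numeric(obs), p_fwe = p_fwe,
    significant = !is.na(p_fwe) & p_fwe <= alpha,
    zero_variance = degenerate)
}

#' Bootstrap stability of the canonical correlation and loadings
#'
#' Subjects are resampled with replacement; residualization is redone per
#' replicate, the imaging set is projected onto the original (fixed) PCA
#' basis -- component-order instability would otherwise dominate -- and the
#' replicate variates are sign-aligned to the original solution by
#' correlation before aggregation. Percentile confidence intervals are
#' returned for the mode-1 canonical correlation and each clinical loading.
#' Replicates with degenerate covariance are skipped and counted.
#'
#' @param fit a [permcca()] result.
#' @param nboot number of bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return object of class `cca_bootstrap`: `r` (estimate, lower, upper),
#'   `loadings` tibble, `n_skipped`.
#' @export
bootstrap_stability <- function(fit, nboot = 1000, seed = 1L, conf = 0.95) {
  stopifnot(inherits(fit, "permcca"))
  inp <- fit$inputs
  n <- fit$n
  if (n < 20L) bg_stop("bootstrap needs at least 20 subjects")
  r_boot <- numeric(nboot)
  l_boot <- matrix(NA_real_, nboot, ncol(inp$y))
  skipped <- 0L
  with_seed(seed, {
    for (i in seq_len(nboot)) {
      idx <- sample.int(n, replace = TRUE)
      ok <- tryCatch({
        Yb <- residualize(inp$y[idx, , drop = FALSE], if (is.null(inp$z_y)) NULL else inp$z_y[idx, , drop = FALSE])
        Xbr <- residualize(inp$x[idx, , drop = FALSE], if (is.null(inp$z_x)) NULL else inp$z_x[idx, , drop = FALSE])
        Xb <- if (is.null(fit$pca)) Xbr else sweep(Xbr, 2, fit$pca$center) %*% fit$pca$rotation
        if (any(apply(Yb, 2, sd) == 0) || any(apply(Xb, 2, sd) == 0)) stop("degenerate")
        cc <- cancor(Yb, Xb)
        v <- scale(Yb, center = cc$xcenter, scale = FALSE) %*% cc$xcoef[, 1]
        s <- sign(as.numeric(cor(v, fit$y_scores[idx, 1])))
        if (!is.finite(s) || s == 0) s <- 1
        r_boot[i] <- cc$cor[1]
        l_boot[i, ] <- s * as.numeric(cor(Yb, v))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) { skipped <- skipped + 1L; r_boot[i] <- NA_real_ }
    }
  })
  if (skipped > 0.05 * nboot) {
    rlang::warn(sprintf("%d/%d bootstrap replicates skipped", skipped, nboot))
  }
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  rq <- quantile(r_boot, probs, na.rm = TRUE, names = FALSE)
  lq <- apply(l_boot, 2, quantile, probs = probs, na.rm = TRUE)
  structure(list(
    r = c(estimate = fit$r[1], lower = rq[1], upper = rq[2]),
    loadings = tibble::tibble(
      variable = colnames(inp$y) %||% paste0("y", seq_len(ncol(inp$y))),
      loading = as.numeric(fit$y_loadings[, 1]),
      lower = lq[1, ], upper = lq[2, ]),
    n_skipped = skipped, nboot = nboot, conf = conf),
    class = "cca_bootstrap")
}

#' @export
print.cca_bootstrap <- function(x, ...) {
  cat(sprintf("<cca_bootstrap> r = %.3f, %g%% CI (%.3f, %.3f); %d skipped\n",
              x$r[1], 100 * x$conf, x$r[2], x$r[3], x$n_skipped))
  invisible(x)
}

#' Regional contributions to the clinical canonical variate
#'
#' Pearson correlation of each region's BAG with the mode-1 clinical
#' canonical variate, quantifying how much each affected region carries the
#' multivariate clinical association.
#'
#' @param fit a [permcca()] result.
#' @param bag samples x regions matrix of regional BAG (same subjects).
#' @return tibble with `region`, `r`, `p_value`, `constant` flag.
#' @export
region_contributions <- function(fit, bag) {
  stopifnot(inherits(fit, "permcca"))
  B <- as.matrix(bag)
  if (nrow(B) != fit$n) bg_stop("bag rows must match the CCA subjects")
  v <- fit$y_scores[, 1]
  constant <- apply(B, 2, sd) == 0
  r <- rep(NA_real_, ncol(B))
  r[!constant] <- as.numeric(cor(B[, !constant, drop = FALSE], v))
  tibble::tibble(region = colnames(B) %||% sprintf("R%03d", seq_len(ncol(B))),
                 r = r, p_value = ifelse(constant, NA_real_, pearson_p(r, fit$n)),
                 constant = constant)
}
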