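#' Tidy a nested-CV report
#' @param x a `cv_report`.
#' @param ... unused.
#' @return per-fold tibble (fold, n, chosen hyperparameters, MAE, R2).
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @return for `glance()`: one-row tibble of averaged metrics.
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(mae = x$mae, r2 = x$r2, r2_adj = x$r2_adj,
                 outer_folds = x$spec$outer_folds,
                 n = nrow(x$predictions))
}

#' Tidy a bias model
#' @param x a `bias_model`.
#' @param ... unused.
#' @method tidy bias_model
#' @export
tidy.bias_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "age"),
                 estimate = c(x$alpha, x$beta))
}

#' @rdname tidy.bias_model
#' @method glance bias_model
#' @export
glance.bias_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, n = x$n, sigma = x$sigma)
}

#' Tidy an ANCOVA result
#' @param x an `ancova_result`.
#' @param ... unused.
#' @return adjusted pairwise group contrasts with Wald intervals.
#' @method tidy ancova_result
#' @export
tidy.ancova_result <- function(x, ...) x$contrasts

#' @rdname tidy.ancova_result
#' @method glance ancova_result
#' @export
glance.ancova_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df[1], df2 = x$df[2],
                 p_value = x$p_value, eta_p2 = x$eta_p2, n = x$n)
}

#' Tidy a permutation CCA fit
#' @param x a `permcca`.
#' @param ... unused.
#' @return per-mode tibble (mode, canonical r, permutation p).
#' @method tidy permcca
#' @export
tidy.permcca <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$r), r = x$r, p_value = x$p)
}

#' @rdname tidy.permcca
#' @method glance permcca
#' @export
glance.permcca <- function(x, ...) {
  tibble::tibble(r1 = x$r[1], p1 = x$p[1], n = x$n, nperm = x$nperm,
                 exhaustive = x$exhaustive,
                 n_components = if (is.null(x$pca)) ncol(x$x_scores) else x$pca$k)
}

#' Tidy a CCA bootstrap
#' @param x a `cca_bootstrap`.
#' @param ... unused.
#' @return clinical loadings with percentile confidence intervals.
#' @method tidy cca_bootstrap
#' @export
tidy.cca_bootstrap <- function(x, ...) x$loadings

#' @rdname tidy.cca_bootstrap
#' @method glance cca_bootstrap
#' @export
glance.cca_bootstrap <- function(x, ...) {
  tibble::tibble(r = x$r[1], conf_low = x$r[2], conf_high = x$r[3],
                 nboot = x$nboot, n_skipped = x$n_skipped)
}
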