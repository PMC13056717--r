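#' Plot out-of-fold predicted vs chronological age
#' @param object a `cv_report`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "chronological age (y)", y = "predicted brain age (y)",
                  subtitle = sprintf("out-of-fold MAE %.2f y, R² %.3f",
                                     object$mae, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot regional group differences along the parcellation
#'
#' Adjusted regional BAG difference per parcel, highlighting parcels
#' surviving FDR correction.
#'
#' @param regional a [regional_ancova()] tibble.
#' @return a ggplot.
#' @export
plot_regional_bag <- function(regional) {
  d <- dplyr::mutate(regional, index = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index, y = .data$estimate,
                                  colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "parcel", y = "adjusted BAG difference (y)",
                  colour = "FDR < 0.05") +
    ggplot2::theme_minimal()
}

#' Plot the first canonical mode
#' @param object a `permcca`.
#' @param ... unused.
#' @return a ggplot of the mode-1 imaging vs clinical variate scores.
#' @method autoplot permcca
#' @export
autoplot.permcca <- function(object, ...) {
  d <- tibble::tibble(clinical = object$y_scores[, 1],
                      imaging = object$x_scores[, 1])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$clinical, y = .data$imaging)) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "black") +
    ggplot2::labs(x = "clinical canonical variate", y = "imaging canonical variate",
                  subtitle = sprintf("r = %.3f, p = %.4g", object$r[1], object$p[1])) +
    ggplot2::theme_minimal()
}

#' Plot bootstrap loading intervals
#' @param object a `cca_bootstrap`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot cca_bootstrap
#' @export
autoplot.cca_bootstrap <- function(object, ...) {
  ggplot2::ggplot(object$loadings,
                  ggplot2::aes(x = .data$loading, y = .data$variable)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "canonical loading", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot behavioural decoding Z scores
#' @param object a `decoding_result`.
#' @param ... unused.
#' @return a ggplot of Z per sub-domain, grouped by domain, with the
#'   significance threshold marked.
#' @method autoplot decoding_result
#' @export
autoplot.decoding_result <- function(object, ...) {
  thr <- attr(object, "z_threshold") %||% 3
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$subdomain,
                                       fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = thr, linetype = 2) +
    ggplot2::labs(x = "Z score", y = NULL, fill = "domain") +
    ggplot2::theme_minimal()
}
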