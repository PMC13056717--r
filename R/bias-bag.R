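#' Fit a brain-age bias model
#'
#' Ordinary least squares of predicted brain age on chronological age within
#' the (normative) training cohort. Predicted brain age regresses toward the
#' training mean (slope < 1), so raw brain-age gaps correlate negatively with
#' age; the fitted intercept/slope define the correction applied downstream.
#' Fit this on out-of-fold training predictions (see
#' [fit_final_models()]), not on in-sample fits, so the correction transfers
#' to new cohorts.
#'
#' @param predicted predicted brain age (years).
#' @param chronological chronological age (years).
#' @return object of class `bias_model` with `alpha` (intercept, years),
#'   `beta` (slope), `n` and `sigma` (residual sd).
#' @export
fit_bias_model <- function(predicted, chronological) {
  stopifnot(length(predicted) == length(chronological))
  ok <- is.finite(predicted) & is.finite(chronological)
  predicted <- predicted[ok]; chronological <- chronological[ok]
  if (length(predicted) < 3L) bg_stop("need at least 3 subjects to fit a bias model")
  if (sd(chronological) == 0) bg_stop("zero variance in chronological age")
  fit <- lm(predicted ~ chronological)
  n <- length(predicted)
  structure(list(alpha = unname(coef(fit)[1]), beta = unname(coef(fit)[2]),
                 n = n, sigma = sqrt(sum(fit$residuals^2) / (n - 2))),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> predicted = %.3f + %.3f * age (n = %d, sigma = %.2f)\n",
              x$alpha, x$beta, x$n, x$sigma))
  invisible(x)
}

#' Bias-correct predictions and compute brain-age gaps
#'
#' The default `"offset"` correction adds the age-dependent offset implied by
#' the bias model: `corrected = predicted + (age - (alpha + beta * age))`.
#' The alternative `"rescale"` variant inverts the regression,
#' `corrected = (predicted - alpha) / beta`, and is provided for sensitivity
#' analysis (unstable when the slope is small). In both cases
#' `BAG = corrected - age`; positive BAG means an older-appearing brain.
#'
#' @param bias a [fit_bias_model()] result (fitted on the normative cohort).
#' @param predicted predicted brain age (years).
#' @param chronological chronological age (years).
#' @param method `"offset"` (default) or `"rescale"`.
#' @return tibble with `age`, `predicted`, `corrected`, `bag`.
#' @export
correct_and_bag <- function(bias, predicted, chronological,
                            method = c("offset", "rescale")) {
  stopifnot(inherits(bias, "bias_model"),
            length(predicted) == length(chronological))
  method <- match.arg(method)
  if (!all(is.finite(predicted)) || !all(is.finite(chronological))) {
    bg_stop("non-finite predicted or chronological age")
  }
  corrected <- switch(method,
    offset = predicted + (chronological - (bias$alpha + bias$beta * chronological)),
    rescale = (predicted - bias$alpha) / bias$beta)
  tibble::tibble(age = chronological, predicted = predicted,
                 corrected = corrected, bag = corrected - chronological)
}

#' Bias models and BAG table for a whole model set
#'
#' Fits one bias model per prediction column (global + each region). By
#' default the final models predict an independent normative *calibration*
#' cohort and the bias regressions are estimated there: fold models are
#' slightly more attenuated than the final model, so cross-validated
#' training predictions systematically understate the application-time
#' slope, whereas a held-out calibration split measures exactly the relation
#' the correction must undo. Omit the calibration arguments to fall back to
#' the training out-of-fold predictions.
#'
#' @param models a [fit_final_models()] result.
#' @param region_means calibration-cohort region means (global model), or
#'   `NULL`.
#' @param voxel_features calibration-cohort voxel features (regional
#'   models), or `NULL`.
#' @param ages calibration-cohort chronological ages (required with either
#'   feature argument).
#' @return named list of `bias_model` objects.
#' @export
fit_bias_models <- function(models, region_means = NULL, voxel_features = NULL,
                            ages = NULL) {
  stopifnot(inherits(models, "trained_model_set"))
  if (is.null(region_means) && is.null(voxel_features)) {
    cvp <- models$cv_predictions
    cols <- setdiff(names(cvp), "age")
    if (!length(cols)) bg_stop("model set has no training predictions")
    return(lapply(stats::setNames(cols, cols),
                  function(cl) fit_bias_model(cvp[[cl]], cvp$age)))
  }
  if (is.null(ages)) bg_stop("calibration `ages` required with calibration features")
  pred <- predict_brain_age(models, region_means = region_means,
                            voxel_features = voxel_features)
  lapply(stats::setNames(names(pred), names(pred)),
         function(cl) fit_bias_model(pred[[cl]], ages))
}

#' @param bias_models a [fit_bias_models()] result.
#' @param predictions tibble from [predict_brain_age()] (columns matching the
#'   bias models).
#' @param chronological chronological ages of the predicted subjects.
#' @param method correction variant, see [correct_and_bag()].
#' @return `bag_table()`: tibble with `age` plus one BAG column (years) per
#'   prediction column.
#' @rdname fit_bias_models
#' @export
bag_table <- function(bias_models, predictions, chronological,
                      method = c("offset", "rescale")) {
  method <- match.arg(method)
  cols <- intersect(names(predictions), names(bias_models))
  if (!length(cols)) bg_stop("no prediction column matches a bias model")
  out <- tibble::tibble(age = chronological)
  for (cl in cols) {
    out[[cl]] <- correct_and_bag(bias_models[[cl]], predictions[[cl]],
                                 chronological, method)$bag
  }
  out
}
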