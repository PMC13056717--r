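#' Specification of the SVR brain-age model and its cross-validation
#'
#' Support vector regression with a radial-basis-function kernel; the cost
#' and kernel-width hyperparameters are searched on a logarithmic grid
#' (powers of ten spanning 0.001--1000 by default) inside the inner
#' cross-validation loop. Folds are stratified by age bins with equal sizes
#' (+/- 1) so each fold preserves the age distribution.
#'
#' @param cost_grid candidate values of the SVR cost parameter C.
#' @param gamma_grid candidate values of the RBF kernel coefficient.
#' @param outer_folds outer CV folds (performance estimation), default 5.
#' @param inner_folds inner CV folds (hyperparameter selection), default 5.
#' @param age_bins number of age-quantile strata used to build folds.
#' @param epsilon half-width of the epsilon-insensitive tube (years).
#' @param seed integer seed controlling fold assignment.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(cost_grid = 10^seq(-3, 3),
                       gamma_grid = 10^seq(-3, 3),
                       outer_folds = 5L, inner_folds = 5L,
                       age_bins = 5L, epsilon = 0.1, seed = 1L) {
  if (!length(cost_grid) || !length(gamma_grid)) {
    bg_stop("hyperparameter grids must be non-empty", class = "braingap_config_error")
  }
  if (outer_folds < 2L || inner_folds < 2L) {
    bg_stop("folds must be >= 2", class = "braingap_config_error")
  }
  structure(list(cost_grid = sort(cost_grid), gamma_grid = sort(gamma_grid),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 age_bins = as.integer(age_bins), epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# equipartitioned age-stratified fold assignment: subjects are ranked into
# age-quantile bins and dealt round-robin (shuffled within bin) across folds
stratified_folds <- function(ages, k, n_bins, seed) {
  n <- length(ages)
  if (n < k) bg_stop("fewer subjects than folds")
  with_seed(seed, {
    if (length(unique(ages)) < 2L) {
      bins <- rep(1L, n)
    } else {
      qs <- unique(quantile(ages, probs = seq(0, 1, length.out = n_bins + 1)))
      bins <- cut(ages, breaks = qs, include.lowest = TRUE, labels = FALSE)
    }
    fold <- integer(n)
    counter <- 0L
    for (b in sort(unique(bins))) {
      ii <- sample(which(bins == b))
      fold[ii] <- ((counter + seq_along(ii) - 1L) %% k) + 1L
      counter <- counter + length(ii)
    }
    fold
  })
}

# fit one standardize-then-SVR model; scaling parameters learned here only
svr_train <- function(X, y, cost, gamma, epsilon) {
  X <- as.matrix(X)
  center <- colMeans(X)
  scl <- apply(X, 2, sd)
  constant <- scl <= 0 | !is.finite(scl)
  scl[constant] <- 1
  fit <- e1071::svm(scale(X, center, scl), y, type = "eps-regression",
                    kernel = "radial", cost = cost, gamma = gamma,
                    epsilon = epsilon, scale = FALSE, fitted = FALSE)
  structure(list(fit = fit, center = center, scale = scl,
                 cost = cost, gamma = gamma, epsilon = epsilon,
                 n_features = ncol(X), n_train = nrow(X),
                 y_mean = mean(y)),
            class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    bg_stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                    object$n_features, ncol(newdata)))
  }
  # a target constant within the eps tube leaves no support vectors; the
  # regression function is then the flat tube centre
  if (object$fit$tot.nSV == 0L) return(rep(object$y_mean, nrow(newdata)))
  as.numeric(predict(object$fit, scale(newdata, object$center, object$scale)))
}

# grid search by k-fold CV MSE; ties broken toward smaller cost, then gamma
# (grids are sorted ascending and only strict improvements replace the best)
grid_search_cv <- function(X, y, spec, fold_ids, folds = spec$inner_folds) {
  best <- NULL
  for (cost in spec$cost_grid) {
    for (gamma in spec$gamma_grid) {
      pred <- numeric(length(y))
      for (f in seq_len(folds)) {
        tr <- fold_ids != f
        m <- svr_train(X[tr, , drop = FALSE], y[tr], cost, gamma, spec$epsilon)
        pred[!tr] <- predict(m, X[!tr, , drop = FALSE])
      }
      mse <- mean((pred - y)^2)
      if (is.null(best) || mse < best$mse - 1e-12) {
        best <- list(cost = cost, gamma = gamma, mse = mse, cv_pred = pred)
      }
    }
  }
  best
}

check_features <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) bg_stop("features contain missing values")
  if (any(apply(X, 2, sd) == 0)) {
    rlang::warn("constant feature column(s); model fit proceeds")
  }
  X
}

#' Nested cross-validated training of a brain-age model
#'
#' Outer folds estimate out-of-sample performance; hyperparameters are chosen
#' independently inside each outer-training set by an inner grid-search CV,
#' so no out-of-fold prediction ever touches a model that saw that subject.
#'
#' @param features subjects x features numeric matrix (region means for the
#'   global model, one region's voxel features for a regional model).
#' @param ages chronological ages (years).
#' @param spec a [model_spec()].
#' @return object of class `cv_report`: per-fold metrics (`folds`),
#'   out-of-fold `predictions`, and averaged `mae`, `r2`, `r2_adj`.
#' @export
nested_cv_train <- function(features, ages, spec = model_spec()) {
  X <- check_features(features)
  stopifnot(length(ages) == nrow(X), all(is.finite(ages)))
  outer <- stratified_folds(ages, spec$outer_folds, spec$age_bins, spec$seed)
  pred <- numeric(length(ages))
  rows <- vector("list", spec$outer_folds)
  for (f in seq_len(spec$outer_folds)) {
    tr <- outer != f
    inner <- stratified_folds(ages[tr], spec$inner_folds, spec$age_bins,
                              spec$seed + f)
    gs <- grid_search_cv(X[tr, , drop = FALSE], ages[tr], spec, inner)
    m <- svr_train(X[tr, , drop = FALSE], ages[tr], gs$cost, gs$gamma, spec$epsilon)
    p <- predict(m, X[!tr, , drop = FALSE])
    pred[!tr] <- p
    y <- ages[!tr]
    ss_res <- sum((p - y)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- 1 - ss_res / ss_tot
    nf <- length(y)
    rows[[f]] <- tibble::tibble(
      fold = f, n = nf, cost = gs$cost, gamma = gs$gamma,
      mae = mean(abs(p - y)), r2 = r2,
      r2_adj = 1 - (1 - r2) * (nf - 1) / (nf - 2))
  }
  folds <- dplyr::bind_rows(rows)
  structure(list(
    folds = folds,
    predictions = tibble::tibble(row = seq_along(ages), age = ages,
                                 predicted = pred, fold = outer),
    mae = mean(folds$mae), r2 = mean(folds$r2), r2_adj = mean(folds$r2_adj),
    spec = spec), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold nested CV: MAE %.3f y, R2 %.3f (adj %.3f)\n",
              x$spec$outer_folds, x$mae, x$r2, x$r2_adj))
  invisible(x)
}

#' Fit the final global and regional brain-age models
#'
#' Hyperparameters are selected by k-fold grid search on the complete
#' training data, the model is refit on all subjects, and the grid search's
#' out-of-fold predictions at the chosen hyperparameters are kept: they are
#' the unbiased training predictions from which the bias model
#' ([fit_bias_model()]) is later estimated.
#'
#' @param region_means subjects x regions matrix (global model input), or
#'   `NULL` to skip the global model.
#' @param ages chronological ages (years).
#' @param voxel_features named list of subjects x voxels matrices (one
#'   regional model each), or `NULL` to skip regional models.
#' @param spec [model_spec()] for the global model.
#' @param regional_spec [model_spec()] for regional models (a reduced grid is
#'   often adequate for the low-dimensional voxel sets).
#' @return object of class `trained_model_set` with elements `global`,
#'   `regional` (named list), `cv_predictions` (tibble with `age`, `global`
#'   and one column per region), and `skipped_regions`.
#' @export
fit_final_models <- function(region_means, ages, voxel_features = NULL,
                             spec = model_spec(), regional_spec = spec) {
  cvp <- tibble::tibble(age = ages)
  global <- NULL
  if (!is.null(region_means)) {
    X <- check_features(region_means)
    fold_ids <- stratified_folds(ages, spec$inner_folds, spec$age_bins, spec$seed)
    gs <- grid_search_cv(X, ages, spec, fold_ids)
    global <- svr_train(X, ages, gs$cost, gs$gamma, spec$epsilon)
    cvp$global <- gs$cv_pred
  }
  regional <- list()
  skipped <- character()
  if (!is.null(voxel_features)) {
    fold_ids <- stratified_folds(ages, regional_spec$inner_folds,
                                 regional_spec$age_bins, regional_spec$seed)
    for (rn in names(voxel_features)) {
      V <- as.matrix(voxel_features[[rn]])
      if (ncol(V) < 2L) {
        skipped <- c(skipped, rn)
        next
      }
      gs <- grid_search_cv(V, ages, regional_spec, fold_ids)
      regional[[rn]] <- svr_train(V, ages, gs$cost, gs$gamma, regional_spec$epsilon)
      cvp[[rn]] <- gs$cv_pred
    }
    if (length(skipped)) {
      rlang::inform(sprintf("regional model skipped for %d region(s) with < 2 voxels",
                            length(skipped)))
    }
  }
  structure(list(global = global, regional = regional, cv_predictions = cvp,
                 spec = spec, regional_spec = regional_spec,
                 skipped_regions = skipped),
            class = "trained_model_set")
}

#' @export
print.trained_model_set <- function(x, ...) {
  cat(sprintf("<trained_model_set> %d model(s): %s%d regional\n",
              (!is.null(x$global)) + length(x$regional),
              if (!is.null(x$global)) "1 global + " else "", length(x$regional)))
  invisible(x)
}

#' Predict global and regional brain age
#'
#' @param models a [fit_final_models()] result.
#' @param region_means subjects x regions matrix for the global model
#'   (`NULL` to skip).
#' @param voxel_features named list of subjects x voxels matrices for the
#'   regional models (`NULL` to skip).
#' @return tibble with one row per subject: `global` and/or one column per
#'   regional model (predicted brain age, years).
#' @export
predict_brain_age <- function(models, region_means = NULL, voxel_features = NULL) {
  stopifnot(inherits(models, "trained_model_set"))
  out <- NULL
  if (!is.null(region_means)) {
    if (is.null(models$global)) bg_stop("model set has no global model")
    out <- tibble::tibble(global = predict(models$global, region_means))
  }
  if (!is.null(voxel_features)) {
    for (rn in names(models$regional)) {
      if (is.null(voxel_features[[rn]])) {
        bg_stop(sprintf("voxel features missing for region %s", rn))
      }
      p <- tryCatch(predict(models$regional[[rn]], voxel_features[[rn]]),
                    error = function(e) {
                      bg_stop(sprintf("region %s: %s", rn, conditionMessage(e)))
                    })
      if (is.null(out)) out <- tibble::tibble(.rows = length(p))
      out[[rn]] <- p
    }
  }
  if (is.null(out)) bg_stop("no features supplied")
  out
}

#' Save / load a trained model set
#'
#' @param models a `trained_model_set`.
#' @param path file path (RDS).
#' @return `save_model_set()` the path, invisibly; `load_model_set()` the
#'   restored model set.
#' @export
save_model_set <- function(models, path) {
  stopifnot(inherits(models, "trained_model_set"))
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_model_set
#' @export
load_model_set <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trained_model_set"))
  m
}
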