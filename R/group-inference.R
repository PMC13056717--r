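# build the covariate model-matrix columns used by the BAG ANCOVA.
# "age2" denotes the quadratic age term; it is computed from centred age
# (limits collinearity with the linear term) when not already a column.
build_covariate_matrix <- function(data, covariates) {
  if (!length(covariates)) return(NULL)
  cols <- list()
  for (cv in covariates) {
    if (cv == "age2" && !"age2" %in% names(data)) {
      if (!"age" %in% names(data)) bg_stop("covariate `age2` needs an `age` column")
      cols[[cv]] <- (data$age - mean(data$age))^2
    } else {
      if (!cv %in% names(data)) bg_stop(sprintf("covariate `%s` not found", cv))
      v <- data[[cv]]
      if (is.numeric(v)) {
        cols[[cv]] <- v
      } else {
        mm <- model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, colnames(mm))
        cols[[cv]] <- mm
      }
    }
  }
  Z <- do.call(cbind, lapply(names(cols), function(nm) {
    m <- as.matrix(cols[[nm]])
    if (ncol(m) == 1L) colnames(m) <- nm
    m
  }))
  qz <- qr(cbind(1, Z))
  if (qz$rank < ncol(Z) + 1L) {
    drop_idx <- setdiff(seq_len(ncol(Z) + 1L), qz$pivot[seq_len(qz$rank)]) - 1L
    bg_stop(paste0("collinear covariate column(s): ",
                   paste(colnames(Z)[drop_idx], collapse = ", ")),
            class = "braingap_rank_error")
  }
  Z
}

#' Covariate-adjusted group comparison of BAG (ANCOVA)
#'
#' Linear model `BAG ~ group + covariates`. For a two-level group the
#' adjusted difference is the group coefficient (second factor level minus
#' first); its F statistic, Wald t confidence interval and partial eta
#' squared `SS_group / (SS_group + SS_residual)` are reported. With more than
#' two levels an omnibus F plus all pairwise adjusted contrasts are returned.
#'
#' @param data data frame with the response, group and covariate columns.
#' @param response name of the BAG column.
#' @param group name of the group column (factor or character).
#' @param covariates character vector of covariate columns; the name `age2`
#'   requests a centred-age-squared term. Default mirrors the standard BAG
#'   adjustment set: age, age squared, sex, TIV and acquisition protocol.
#' @param conf_level confidence level for the Wald interval.
#' @return object of class `ancova_result`.
#' @export
ancova_compare <- function(data, response = "bag", group = "group",
                           covariates = c("age", "age2", "sex", "tiv_ml", "protocol"),
                           conf_level = 0.95) {
  y <- data[[response]]
  if (is.null(y)) bg_stop(sprintf("response `%s` not found", response))
  g <- factor(data[[group]])
  if (nlevels(g) < 2L) bg_stop("need at least two groups")
  Z <- build_covariate_matrix(data, covariates)
  G <- model.matrix(~g)[, -1, drop = FALSE]
  colnames(G) <- levels(g)[-1]
  ones <- rep(1, length(y))
  X_full <- cbind(`(Intercept)` = ones, G, Z)
  X_red <- cbind(`(Intercept)` = ones, Z)
  qf <- qr(X_full)
  if (qf$rank < ncol(X_full)) {
    bg_stop("rank-deficient design (group confounded with covariates)",
            class = "braingap_rank_error")
  }
  res_f <- qr.resid(qf, y)
  res_r <- qr.resid(qr(X_red), y)
  sse_f <- sum(res_f^2)
  sse_r <- sum(res_r^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - ncol(X_full)
  fstat <- ((sse_r - sse_f) / df1) / (sse_f / df2)
  pval <- pf(fstat, df1, df2, lower.tail = FALSE)
  eta <- (sse_r - sse_f) / sse_r

  beta <- qr.coef(qf, y)
  sigma2 <- sse_f / df2
  XtXinv <- chol2inv(qr.R(qf))
  se_all <- sqrt(diag(XtXinv) * sigma2)
  names(se_all) <- colnames(X_full)
  tcrit <- qt(1 - (1 - conf_level) / 2, df2)

  # pairwise adjusted contrasts (levels j vs i) from the full-model fit
  lev <- levels(g)
  pair_rows <- list()
  for (i in seq_len(nlevels(g) - 1L)) {
    for (j in seq(i + 1L, nlevels(g))) {
      ci <- if (i == 1L) 0 else beta[lev[i]]
      cj <- beta[lev[j]]
      est <- unname(cj - ci)
      idx_i <- if (i == 1L) NULL else which(colnames(X_full) == lev[i])
      idx_j <- which(colnames(X_full) == lev[j])
      v <- sigma2 * (XtXinv[idx_j, idx_j] +
                       (if (is.null(idx_i)) 0 else
                         XtXinv[idx_i, idx_i] - 2 * XtXinv[idx_j, idx_i]))
      se <- sqrt(v)
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        contrast = paste(lev[j], "-", lev[i]), estimate = est,
        conf_low = est - tcrit * se, conf_high = est + tcrit * se,
        statistic = est / se, p_value = 2 * pt(abs(est / se), df2, lower.tail = FALSE))
    }
  }
  contrasts <- dplyr::bind_rows(pair_rows)

  coefs <- tibble::tibble(term = colnames(X_full), estimate = unname(beta),
                          std_error = unname(se_all))
  structure(list(
    estimate = if (nlevels(g) == 2L) contrasts$estimate[1] else NA_real_,
    conf_low = if (nlevels(g) == 2L) contrasts$conf_low[1] else NA_real_,
    conf_high = if (nlevels(g) == 2L) contrasts$conf_high[1] else NA_real_,
    statistic = fstat, df = c(df1, df2), p_value = pval, eta_p2 = eta,
    contrasts = contrasts, coefficients = coefs,
    n = length(y), groups = lev, conf_level = conf_level,
    response = response), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova_result> F(%d, %d) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
              x$df[1], x$df[2], x$statistic, x$p_value, x$eta_p2))
  if (length(x$groups) == 2L) {
    cat(sprintf("  adjusted difference (%s - %s) = %.3f y, %g%% CI (%.2f, %.2f)\n",
                x$groups[2], x$groups[1], x$estimate, 100 * x$conf_level,
                x$conf_low, x$conf_high))
  }
  invisible(x)
}

#' Parcel-wise ANCOVA with FDR control
#'
#' Runs the covariate-adjusted two-group ANCOVA of [ancova_compare()]
#' independently for every regional BAG column (a single QR decomposition is
#' shared across regions) and applies Benjamini--Hochberg FDR control across
#' all parcels.
#'
#' @param bag subjects x regions matrix (or data frame) of regional BAG.
#' @param data subject table aligned with `bag` rows.
#' @param group,covariates,conf_level as in [ancova_compare()].
#' @param q FDR level (default 0.05).
#' @return tibble with one row per region: adjusted difference, F, p, partial
#'   eta squared, BH-adjusted p and significance flag.
#' @export
regional_ancova <- function(bag, data, group = "group",
                            covariates = c("age", "age2", "sex", "tiv_ml", "protocol"),
                            q = 0.05, conf_level = 0.95) {
  Y <- as.matrix(bag)
  g <- factor(data[[group]])
  if (nlevels(g) != 2L) bg_stop("regional ANCOVA expects exactly two groups")
  Z <- build_covariate_matrix(data, covariates)
  G <- model.matrix(~g)[, -1, drop = FALSE]
  ones <- rep(1, nrow(Y))
  X_full <- cbind(ones, G, Z)
  X_red <- cbind(ones, Z)
  qf <- qr(X_full); qr_ <- qr(X_red)
  if (qf$rank < ncol(X_full)) bg_stop("rank-deficient design", class = "braingap_rank_error")
  res_f <- qr.resid(qf, Y); res_r <- qr.resid(qr_, Y)
  sse_f <- colSums(res_f^2); sse_r <- colSums(res_r^2)
  df2 <- nrow(Y) - ncol(X_full)
  fstat <- (sse_r - sse_f) / (sse_f / df2)
  pval <- pf(fstat, 1, df2, lower.tail = FALSE)
  eta <- (sse_r - sse_f) / sse_r
  beta <- qr.coef(qf, Y)
  gi <- 2L  # group column position in X_full
  XtXinv <- chol2inv(qr.R(qf))
  se <- sqrt(XtXinv[gi, gi] * sse_f / df2)
  tcrit <- qt(1 - (1 - conf_level) / 2, df2)
  sel <- fdr_select(pval, q)
  tibble::tibble(
    region = colnames(Y) %||% sprintf("R%03d", seq_along(pval)),
    estimate = unname(beta[gi, ]), conf_low = unname(beta[gi, ] - tcrit * se),
    conf_high = unname(beta[gi, ] + tcrit * se),
    statistic = unname(fstat), p_value = unname(pval), eta_p2 = unname(eta),
    p_fdr = sel$p_adj, significant = sel$significant)
}

#' Benjamini--Hochberg FDR selection
#'
#' Step-up FDR control: adjusted p-values via [stats::p.adjust()] and the
#' selected set `p_adj <= q` (equivalent to the classical step-up rule).
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param q FDR level.
#' @return tibble with `p`, `p_adj`, `significant`.
#' @export
fdr_select <- function(p_values, q = 0.05) {
  if (!length(p_values)) bg_stop("empty p-value vector")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    bg_stop("p-values must lie in [0, 1]")
  }
  adj <- p.adjust(p_values, method = "BH")
  tibble::tibble(p = p_values, p_adj = adj, significant = adj <= q)
}

#' Protocol-stratified group comparison
#'
#' Runs [ancova_compare()] separately within each level of `stratum`
#' (dropping the stratum from the covariate set). Strata missing one of the
#' groups are skipped with a warning.
#'
#' @param data subject table including the response.
#' @param response,group,covariates,conf_level as in [ancova_compare()].
#' @param stratum stratifying column (default `"protocol"`).
#' @return tibble with one row per analysed stratum (estimate, CI, F, p,
#'   partial eta squared, n); full `ancova_result` objects in the
#'   `"results"` attribute.
#' @export
stratified_compare <- function(data, response = "bag", group = "group",
                               covariates = c("age", "age2", "sex", "tiv_ml", "protocol"),
                               stratum = "protocol", conf_level = 0.95) {
  covs <- setdiff(covariates, stratum)
  pieces <- split(seq_len(nrow(data)), data[[stratum]])
  results <- list()
  rows <- list()
  for (s in names(pieces)) {
    d <- data[pieces[[s]], , drop = FALSE]
    if (length(unique(d[[group]])) < 2L) {
      rlang::warn(sprintf("stratum `%s` lacks both groups; skipped", s))
      next
    }
    a <- ancova_compare(d, response, group, covs, conf_level)
    results[[s]] <- a
    rows[[s]] <- tibble::tibble(stratum = s, estimate = a$estimate,
                                conf_low = a$conf_low, conf_high = a$conf_high,
                                statistic = a$statistic, p_value = a$p_value,
                                eta_p2 = a$eta_p2, n = a$n)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "results") <- results
  out
}
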