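# internal helpers shared across modules

# error with a consistent class so tests can target braingap conditions
bg_stop <- function(msg, class = "braingap_error") {
  rlang::abort(msg, class = class)
}

assert_scalar_number <- function(x, field, min = -Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < min) {
    bg_stop(sprintf("invalid configuration: `%s` must be a %s number >= %s",
                    field, if (finite) "finite" else "", format(min)),
            class = "braingap_config_error")
  }
  invisible(x)
}

# seeded evaluation that does not clobber the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# residual-forming OLS used by several modules; X gains an intercept column
ols_residuals <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bg_stop("rank-deficient design in residualization", class = "braingap_rank_error")
  }
  as.matrix(qr.resid(qr_x, as.matrix(y)))
}

pearson_p <- function(r, n) {
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
}
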