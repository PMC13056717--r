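BEHAVIOURAL_DOMAINS <- c("action", "cognition", "emotion", "interoception",
                         "perception")

#' Load a labelled activation-foci database
#'
#' Reads a TSV of stereotaxic activation foci, each labelled with one of the
#' five primary behavioural domains (action, cognition, emotion,
#' interoception, perception) and a constituent sub-domain. Duplicate foci
#' are permitted; unknown domains are rejected with the offending row number.
#'
#' @param path TSV file with columns `x_mm`, `y_mm`, `z_mm`, `domain`,
#'   `subdomain`, `source`, `space`. A small synthetic example database (59
#'   sub-domains, MNI space) ships with the package:
#'   `system.file("extdata", "synthetic_foci_mni.tsv", package = "braingap")`.
#' @return tibble of class `foci_database`; the stereotaxic space tag is
#'   stored in the `"space"` attribute.
#' @export
load_foci_db <- function(path) {
  db <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("x_mm", "y_mm", "z_mm", "domain", "subdomain", "source", "space")
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols)) {
    bg_stop(paste0("foci database missing column(s): ",
                   paste(missing_cols, collapse = ", ")))
  }
  if (!nrow(db)) bg_stop("empty foci database")
  bad <- which(!db$domain %in% BEHAVIOURAL_DOMAINS)
  if (length(bad)) {
    bg_stop(sprintf("unknown domain %s in row %d", dQuote(db$domain[bad[1]]), bad[1]))
  }
  if (!all(is.finite(db$x_mm) & is.finite(db$y_mm) & is.finite(db$z_mm))) {
    bg_stop("non-finite focus coordinates")
  }
  if (length(unique(db$subdomain)) > 59L) {
    bg_stop("more than 59 sub-domains in database")
  }
  nest <- unique(db[, c("domain", "subdomain")])
  if (anyDuplicated(nest$subdomain)) {
    bg_stop("sub-domain assigned to more than one domain")
  }
  if (length(unique(db$space)) > 1L) bg_stop("mixed stereotaxic spaces in database")
  structure(tibble::as_tibble(db), space = db$space[1],
            class = c("foci_database", class(tibble::tibble())))
}

#' Write a foci database to TSV
#' @param db a `foci_database` tibble.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_foci_db <- function(db, path) {
  readr::write_tsv(db, path)
  invisible(path)
}

#' Meta-analytic behavioural decoding of an ROI mask
#'
#' A focus lies in the ROI if its nearest voxel (world-to-voxel via the
#' inverse affine, rounded; optional dilation radius in mm) is true in the
#' mask. For each sub-domain with database count K of N total foci and k of
#' the n in-ROI foci, the spatial-probability Z score compares the in-ROI
#' proportion to the database base rate p0 = K/N under the binomial null:
#' `Z = (k - n p0) / sqrt(n p0 (1 - p0))`. A two-sided exact binomial p is
#' co-reported so the normal approximation is auditable. The fixed decision
#' rule `Z > z_threshold` (default 3.0) corresponds to Bonferroni control at
#' 0.05 across the 59 sub-domains.
#'
#' @param mask logical/0-1 3-D array or NIfTI image (nonempty).
#' @param db a [load_foci_db()] database.
#' @param affine 4x4 voxel-to-world affine (0-based voxel indices); defaults
#'   to the mask's NIfTI transform, or identity for a plain array.
#' @param z_threshold significance threshold on Z (default 3.0).
#' @param dilate_mm count foci within this distance (mm) of the ROI surface
#'   by dilating the search to neighbouring voxels; 0 (default) = nearest
#'   voxel only.
#' @param space stereotaxic space tag of the mask; must match the database.
#' @return tibble of class `decoding_result`: per sub-domain `domain`,
#'   `subdomain`, `k` (in-ROI), `n` (ROI total), `K`, `N`, `p0`, `z`,
#'   `p_exact`, `significant`; attributes record the ROI focus count and
#'   skipped sub-domains.
#' @export
decode_roi <- function(mask, db, affine = NULL, z_threshold = 3.0,
                       dilate_mm = 0, space = NULL) {
  stopifnot(inherits(db, "foci_database"))
  if (is.null(affine) && inherits(mask, "niftiImage")) {
    affine <- structure(RNifti::xform(mask), class = NULL)
  }
  mask_arr <- array(as_volume(mask) > 0, dim(as_volume(mask)))
  if (!any(mask_arr)) bg_stop("empty ROI mask")
  if (is.null(affine)) affine <- diag(4)
  if (is.null(space)) space <- attr(mask, "space")
  db_space <- attr(db, "space")
  if (!is.null(space) && !is.null(db_space) && !identical(space, db_space)) {
    bg_stop(sprintf("space mismatch: mask is %s, database is %s", space, db_space))
  }

  inv <- solve(affine)
  xyz1 <- rbind(db$x_mm, db$y_mm, db$z_mm, 1)
  vox <- inv %*% xyz1                      # 0-based voxel coordinates
  dims <- dim(mask_arr)
  in_roi <- logical(nrow(db))
  # voxel size along each axis, for the dilation radius
  vsize <- sqrt(colSums(affine[1:3, 1:3]^2))
  reach <- if (dilate_mm > 0) ceiling(dilate_mm / vsize) else c(0L, 0L, 0L)
  offs <- expand.grid(dx = -reach[1]:reach[1], dy = -reach[2]:reach[2],
                      dz = -reach[3]:reach[3])
  for (i in seq_len(nrow(db))) {
    v0 <- round(vox[1:3, i]) + 1          # 1-based array indices
    for (o in seq_len(nrow(offs))) {
      v <- v0 + as.numeric(offs[o, ])
      if (all(v >= 1) && all(v <= dims) && mask_arr[v[1], v[2], v[3]]) {
        in_roi[i] <- TRUE
        break
      }
    }
  }

  n_roi <- sum(in_roi)
  N <- nrow(db)
  sub_tab <- dplyr::distinct(db[, c("domain", "subdomain")])
  rows <- skipped <- list()
  for (i in seq_len(nrow(sub_tab))) {
    sd_i <- sub_tab$subdomain[i]
    K <- sum(db$subdomain == sd_i)
    p0 <- K / N
    if (p0 <= 0) {
      skipped[[length(skipped) + 1L]] <- sd_i
      next
    }
    k <- sum(db$subdomain == sd_i & in_roi)
    if (n_roi > 0) {
      z <- (k - n_roi * p0) / sqrt(n_roi * p0 * (1 - p0))
      p_exact <- binom.test(k, n_roi, p0)$p.value
    } else {
      z <- NA_real_; p_exact <- NA_real_
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      domain = sub_tab$domain[i], subdomain = sd_i,
      k = k, n = n_roi, K = K, N = N, p0 = p0, z = z, p_exact = p_exact,
      significant = !is.na(z) & z > z_threshold)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_roi") <- n_roi
  attr(out, "no_foci") <- n_roi == 0L
  attr(out, "skipped_subdomains") <- unlist(skipped)
  attr(out, "z_threshold") <- z_threshold
  if (n_roi == 0L) rlang::warn("ROI contains zero foci; Z undefined")
  class(out) <- c("decoding_result", class(out))
  out
}
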