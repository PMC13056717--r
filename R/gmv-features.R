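#' Build a grey-matter mask from a probability map
#'
#' Voxels with grey-matter probability strictly greater than `threshold` are
#' retained; the conventional 0.2 cutoff excludes low-probability grey-matter
#' voxels.
#'
#' @param probability_map 3-D array (or NIfTI image / path readable by
#'   RNifti) of probabilities in \[0, 1\].
#' @param threshold inclusion threshold (strict `>`), default 0.2.
#' @return logical 3-D array of class `gm_mask` with the threshold stored as
#'   an attribute.
#' @export
build_gm_mask <- function(probability_map, threshold = 0.2) {
  prob <- as_volume(probability_map)
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    bg_stop("probability map values must lie in [0, 1]")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 || threshold > 1) {
    bg_stop("`threshold` must be a single probability")
  }
  mask <- prob > threshold
  if (!any(mask)) bg_stop("mask is empty: no voxel exceeds the threshold")
  structure(mask, threshold = threshold, class = c("gm_mask", class(mask)))
}

# coerce path / RNifti image / array to a plain numeric array
as_volume <- function(x) {
  if (is.character(x)) x <- RNifti::readNifti(x)
  a <- unclass(as.array(x))
  attributes(a) <- list(dim = dim(a))
  a
}

#' Extract region-mean and voxel-wise GMV features
#'
#' For every atlas parcel, collects the masked in-parcel voxel values of each
#' subject's GMV map in the array's native (column-major) linear order --
#' fixed so voxel-wise feature columns are comparable across subjects -- and
#' their arithmetic mean. Parcels left with zero voxels after masking are
#' dropped from both feature sets and reported.
#'
#' @param gmv_maps list of 3-D arrays, NIfTI images, or file paths (one per
#'   subject); all must share the atlas grid.
#' @param atlas integer-labelled 3-D volume (labels > 0), same grid.
#' @param mask a [build_gm_mask()] result (or logical array), same grid;
#'   `NULL` keeps all voxels.
#' @param subject_ids optional character vector of row names.
#' @return object of class `region_feature_set`: list with `region_means`
#'   (subjects x regions matrix), `voxel_features` (named list of subjects x
#'   voxels matrices), `regions` (label order) and `dropped_regions`.
#' @export
extract_features <- function(gmv_maps, atlas, mask = NULL, subject_ids = NULL) {
  atlas_arr <- as_volume(atlas)
  if (is.null(mask)) {
    mask_arr <- array(TRUE, dim(atlas_arr))
  } else {
    mask_arr <- array(as.logical(mask), dim(as_volume(mask)))
  }
  if (!identical(dim(atlas_arr), dim(mask_arr))) {
    bg_stop("alignment error: atlas and mask grids differ")
  }
  if (!is.list(gmv_maps)) gmv_maps <- as.list(gmv_maps)
  n <- length(gmv_maps)
  if (n == 0L) bg_stop("no GMV maps supplied")

  labels <- sort(unique(atlas_arr[atlas_arr > 0]))
  region_names <- sprintf("R%03d", labels)
  # fixed scan order: column-major linear indices within each labelled parcel
  idx_by_region <- lapply(labels, function(l) which(atlas_arr == l & mask_arr))
  names(idx_by_region) <- region_names
  keep <- lengths(idx_by_region) > 0L
  dropped <- region_names[!keep]
  if (length(dropped)) {
    rlang::warn(sprintf("%d region(s) removed entirely by the mask: %s",
                        length(dropped), paste(dropped, collapse = ", ")))
  }
  idx_by_region <- idx_by_region[keep]
  region_names <- region_names[keep]

  vox <- lapply(idx_by_region, function(ii) matrix(NA_real_, n, length(ii)))
  for (s in seq_len(n)) {
    vol <- as_volume(gmv_maps[[s]])
    if (!identical(dim(vol), dim(atlas_arr))) {
      bg_stop(sprintf("alignment error: GMV map %d grid differs from atlas", s))
    }
    for (r in seq_along(idx_by_region)) vox[[r]][s, ] <- vol[idx_by_region[[r]]]
  }
  means <- vapply(vox, rowMeans, numeric(n))
  if (n == 1L) means <- matrix(means, nrow = 1, dimnames = list(NULL, region_names))
  if (anyNA(means)) bg_stop("NaN/NA voxel values inside the mask")
  rownames(means) <- subject_ids
  structure(list(region_means = means, voxel_features = vox,
                 regions = region_names, dropped_regions = dropped),
            class = "region_feature_set")
}

#' @export
print.region_feature_set <- function(x, ...) {
  cat(sprintf("<region_feature_set> %d subjects x %d regions (%d dropped)\n",
              nrow(x$region_means), length(x$regions), length(x$dropped_regions)))
  invisible(x)
}
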