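## Volume / mask I/O and ROI patch extraction.
##
## The pipeline consumes spatially pre-aligned volume/mask pairs (the
## normalization to a standard grid is upstream, outside this package);
## only shape agreement is checked here.

#' Load a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 image into an intensity volume. Intensities are
#' passed through unmodified; non-finite voxels are treated as a data
#' error rather than silently propagated into texture matrices.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An object of class `intensity_volume`: list with `data`
#'   (3-D numeric array), `spacing` (voxel size in mm per axis) and
#'   `affine` (4x4 grid-to-world transform).
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  if (length(dim(data)) == 4L && dim(data)[4] == 1L) {
    data <- array(data, dim(data)[1:3])
  }
  if (length(dim(data)) != 3L) {
    stop("expected a 3-D image, got ", length(dim(data)),
         " dimensions: ", path)
  }
  if (!all(is.finite(data))) {
    idx <- which(!is.finite(data), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite voxel at index (%d, %d, %d) in %s",
                 idx[1], idx[2], idx[3], path))
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    spacing <- rep(1, 3)
  }
  structure(list(data = data, spacing = spacing,
                 affine = structure(RNifti::xform(img), class = NULL)),
            class = "intensity_volume")
}

#' Load a binary ROI mask
#'
#' @param path NIfTI file with values in \{0, 1\}.
#' @param label subregion label, one of `left_caudal`, `left_head`,
#'   `right_caudal`, `right_head`.
#' @param min_voxels minimum foreground size; smaller ROIs are rejected
#'   because 3-D texture matrices degenerate on them.
#' @return Object of class `roi_mask`: list with binary `data` and `label`.
#' @export
load_mask <- function(path, label, min_voxels = 27L) {
  label <- match.arg(label, names(subregion_codes()))
  vol <- load_volume(path)
  as_roi_mask(vol$data, label, min_voxels = min_voxels)
}

#' Construct an ROI mask from an array
#'
#' @param data 3-D array with values in \{0, 1\}.
#' @inheritParams load_mask
#' @return Object of class `roi_mask`.
#' @export
as_roi_mask <- function(data, label, min_voxels = 27L) {
  label <- match.arg(label, names(subregion_codes()))
  if (length(dim(data)) != 3L) stop("mask must be 3-D")
  u <- unique(as.vector(data))
  if (!all(u %in% c(0, 1))) stop("mask values must be 0 or 1")
  n_fg <- sum(data)
  if (n_fg < min_voxels) {
    stop("ROI '", label, "' has ", n_fg, " foreground voxels; at least ",
         min_voxels, " are required for 3-D texture statistics")
  }
  structure(list(data = array(as.integer(data), dim(data)), label = label),
            class = "roi_mask")
}

#' Extract a masked bounding-box patch
#'
#' Crops the volume to the tight bounding box of the mask's foreground and
#' carries the cropped mask alongside, so downstream statistics can be
#' restricted to foreground voxels (excluded, not merely zeroed). This is
#' the in-memory equivalent of masking a normalized image with an
#' atlas-derived subregion mask.
#'
#' @param volume an `intensity_volume` (or bare 3-D array).
#' @param mask an `roi_mask`.
#' @return Object of class `roi_patch`: list with `values` (cropped
#'   intensities), `mask` (cropped binary array), `label`, `n_voxels`.
#' @export
extract_roi <- function(volume, mask) {
  data <- if (inherits(volume, "intensity_volume")) volume$data else volume
  if (!inherits(mask, "roi_mask")) stop("mask must be an 'roi_mask'")
  if (!identical(dim(data), dim(mask$data))) {
    stop("volume and mask shapes differ: ",
         paste(dim(data), collapse = "x"), " vs ",
         paste(dim(mask$data), collapse = "x"))
  }
  m <- mask$data
  if (sum(m) == 0L) stop("empty ROI mask for '", mask$label, "'")
  idx <- which(m == 1L, arr.ind = TRUE)
  lo <- unname(apply(idx, 2, min))
  hi <- unname(apply(idx, 2, max))
  vals <- data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dim(vals) <- hi - lo + 1L
  dim(msk) <- hi - lo + 1L
  structure(list(values = vals, mask = msk, label = mask$label,
                 n_voxels = sum(msk)),
            class = "roi_patch")
}

#' @export
print.roi_patch <- function(x, ...) {
  cat(sprintf("<roi_patch '%s': %s box, %d foreground voxels>\n",
              x$label, paste(dim(x$values), collapse = "x"), x$n_voxels))
  invisible(x)
}

patch_foreground <- function(patch) patch$values[patch$mask == 1L]

#' Load a cohort from a manifest
#'
#' Reads the manifest CSV (columns `subject_id`, `group`, `age`, `gender`,
#' `mmse`, optional `avlt_ir`, `avlt_dr`, `avlt_rp`, `avlt_rn`, `vol_path`,
#' `mask_lc`, `mask_lh`, `mask_rc`, `mask_rh`), loads each subject's volume
#' and four subregion masks, and extracts the four ROI patches.
#'
#' @param manifest path to the manifest CSV. Relative file paths are
#'   resolved against the manifest's directory.
#' @return Object of class `cohort`: list with `subjects` (per subject: id
#'   plus a named list of 4 `roi_patch`) and `covariates` (data.frame, one
#'   row per subject in manifest order).
#' @export
load_cohort <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "age", "gender", "mmse", "vol_path",
           "mask_lc", "mask_lh", "mask_rc", "mask_rh")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$subject_id)) {
    stop("duplicated subject id(s): ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]),
               collapse = ", "))
  }
  bad_grp <- setdiff(unique(tab$group), c("AD", "aMCI", "NC"))
  if (length(bad_grp)) stop("unknown group label(s): ",
                            paste(bad_grp, collapse = ", "))
  root <- dirname(manifest)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(root, p))
  mask_cols <- c(left_caudal = "mask_lc", left_head = "mask_lh",
                 right_caudal = "mask_rc", right_head = "mask_rh")
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    vol <- load_volume(resolve(row$vol_path))
    patches <- lapply(names(mask_cols), function(lab) {
      mpath <- row[[mask_cols[[lab]]]]
      if (is.na(mpath) || !nzchar(mpath) ||
          !file.exists(resolve(mpath))) {
        stop("subject '", row$subject_id, "' is missing the ", lab,
             " mask")
      }
      extract_roi(vol, load_mask(resolve(mpath), lab))
    })
    names(patches) <- names(mask_cols)
    list(subject_id = row$subject_id, patches = patches)
  })
  cov_cols <- intersect(
    c("subject_id", "group", "age", "gender", "mmse",
      "avlt_ir", "avlt_dr", "avlt_rp", "avlt_rn"), names(tab))
  structure(list(subjects = subjects,
                 covariates = tab[, cov_cols, drop = FALSE]),
            class = "cohort")
}
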