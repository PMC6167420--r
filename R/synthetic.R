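## Synthetic cohort generator: Gaussian-random-field phantoms with
## group-dependent texture (correlation length), intensity shift,
## demographics and cognition scores, emitting exactly the volume/mask/
## manifest schema the rest of the pipeline consumes.
##
## The texture knob is the sd (in voxels) of the Gaussian kernel that
## smooths a white-noise field: longer correlation lowers GLCM
## contrast/entropy, mimicking disease-related texture change without
## claiming anatomical fidelity.

#' Synthetic cohort configuration
#'
#' Defaults reproduce the cohort structure of the modeled study
#' population: group sizes 45/33/38 (NC/aMCI/AD), group-balanced age and
#' gender, MMSE and four AVLT scores decreasing with disease severity.
#' The `effect` multiplier scales every disease effect (texture
#' correlation-length and intensity-shift deviations from NC): 0 gives an
#' exchangeable null cohort, 1 the default planted effect.
#'
#' @param n_per_group named integer vector (`NC`, `aMCI`, `AD`).
#' @param vol_dim volume grid dimensions (voxels).
#' @param semi_axes ellipsoid ROI semi-axes (voxels).
#' @param base_mean baseline ROI intensity mean (arbitrary units).
#' @param base_sd voxelwise intensity heterogeneity sd.
#' @param smooth_sigma per-group Gaussian-field smoothing sd in voxels
#'   (NC, aMCI, AD); differences are the texture effect.
#' @param intensity_shift per-group additive intensity shift.
#' @param effect effect-size multiplier applied to deviations from NC.
#' @param age_mean,age_sd,p_male,mmse_mean,mmse_sd per-group covariate
#'   models (order NC, aMCI, AD).
#' @param avlt per-score list of per-group `mean`/`sd` for the four AVLT
#'   scores (immediate recall, delayed recall, recognition of primary and
#'   new words).
#' @param seed RNG seed; (config, seed) fully determines the cohort.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(NC = 45L, aMCI = 33L, AD = 38L),
                          vol_dim = c(40L, 40L, 18L),
                          semi_axes = c(8, 6, 5),
                          base_mean = 100,
                          base_sd = 10,
                          smooth_sigma = c(NC = 1.0, aMCI = 1.15,
                                           AD = 1.3),
                          intensity_shift = c(NC = 0, aMCI = -3,
                                              AD = -6),
                          effect = 1,
                          age_mean = c(68.2, 70.6, 71.7),
                          age_sd = c(6.9, 8.2, 8.3),
                          p_male = c(0.49, 0.42, 0.42),
                          mmse_mean = c(28.6, 26.6, 17.6),
                          mmse_sd = c(1.4, 2.6, 5.6),
                          avlt = list(
                            avlt_ir = list(mean = c(5.6, 4.2, 3.0),
                                           sd = c(1.2, 1.4, 1.3)),
                            avlt_dr = list(mean = c(5.6, 2.5, 0.6),
                                           sd = c(1.9, 2.3, 1.1)),
                            avlt_rp = list(mean = c(9.4, 8.4, 6.2),
                                           sd = c(1.1, 1.5, 3.5)),
                            avlt_rn = list(mean = c(9.8, 8.7, 6.8),
                                           sd = c(0.7, 2.1, 3.2))),
                          seed = 1L) {
  stopifnot(all(n_per_group >= 2), all(c("NC", "aMCI", "AD") %in%
                                         names(n_per_group)),
            base_sd >= 0, all(smooth_sigma > 0), effect >= 0,
            all(age_sd >= 0), all(mmse_sd >= 0))
  structure(as.list(environment()), class = "cohort_config")
}

## Circulant Gaussian smoothing operator for one axis (periodic wrap).
gauss_operator <- function(n, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  offs <- -half:half
  w <- exp(-offs^2 / (2 * sigma^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (r in seq_len(n)) {
    pos <- ((r - 1 + offs) %% n) + 1
    for (m in seq_along(offs)) S[r, pos[m]] <- S[r, pos[m]] + w[m]
  }
  S
}

smooth_field <- function(noise, sigma) {
  out <- noise
  for (axis in 1:3) {
    S <- gauss_operator(dim(noise)[axis], sigma)
    out <- apply_axis(out, axis, function(m) S %*% m)
  }
  out
}

ellipsoid_mask <- function(vol_dim, center, semi_axes) {
  i <- array(rep(seq_len(vol_dim[1]), times = prod(vol_dim[2:3])),
             vol_dim)
  j <- aperm(array(rep(seq_len(vol_dim[2]),
                       times = prod(vol_dim[c(1, 3)])),
                   vol_dim[c(2, 1, 3)]), c(2, 1, 3))
  k <- aperm(array(rep(seq_len(vol_dim[3]),
                       times = prod(vol_dim[1:2])),
                   vol_dim[c(3, 1, 2)]), c(2, 3, 1))
  d2 <- ((i - center[1]) / semi_axes[1])^2 +
        ((j - center[2]) / semi_axes[2])^2 +
        ((k - center[3]) / semi_axes[3])^2
  array(as.integer(d2 <= 1), vol_dim)
}

## Fixed subregion mask geometry for a config (shared by all subjects).
cohort_masks <- function(config) {
  d <- config$vol_dim
  qx <- round(d[1] * c(0.28, 0.72))
  qy <- round(d[2] * c(0.28, 0.72))
  cz <- round(d[3] / 2)
  centers <- list(left_caudal  = c(qx[1], qy[1], cz),
                  left_head    = c(qx[1], qy[2], cz),
                  right_caudal = c(qx[2], qy[1], cz),
                  right_head   = c(qx[2], qy[2], cz))
  lapply(names(centers), function(lab)
    as_roi_mask(ellipsoid_mask(d, centers[[lab]], config$semi_axes),
                lab)) |> stats::setNames(names(centers))
}

rnorm_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic cohort
#'
#' Draws, per subject, a smoothed Gaussian random field (smoothing sd set
#' by the subject's group, scaled by `effect`) plus the group intensity
#' shift over the whole volume; the four fixed ellipsoidal subregion
#' masks cut the ROI patches. Covariates, MMSE and AVLT scores are drawn
#' from the per-group models. Fully reproducible from (config, seed).
#'
#' @param config a [cohort_config()].
#' @return Object of class `cohort` (same contract as [load_cohort()]):
#'   `subjects` (id + 4 patches), `covariates`, plus `volumes`, `masks`
#'   and `config` for writing to disk via [write_cohort()].
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  masks <- cohort_masks(config)
  grp_order <- c("NC", "aMCI", "AD")
  n <- config$n_per_group[grp_order]
  groups <- rep(grp_order, times = n)
  N <- length(groups)
  gi <- match(groups, grp_order)  # severity index 1, 2, 3
  eff <- config$effect
  sigma_g <- config$smooth_sigma[["NC"]] +
    eff * (config$smooth_sigma[grp_order] - config$smooth_sigma[["NC"]])
  shift_g <- eff * config$intensity_shift[grp_order]
  volumes <- vector("list", N)
  subjects <- vector("list", N)
  ids <- sprintf("S%03d", seq_len(N))
  for (s in seq_len(N)) {
    noise <- array(stats::rnorm(prod(config$vol_dim)), config$vol_dim)
    field <- smooth_field(noise, sigma_g[gi[s]])
    field <- field / stats::sd(field) * config$base_sd
    vol <- field + config$base_mean + shift_g[gi[s]]
    volumes[[s]] <- vol
    patches <- lapply(masks, function(m) extract_roi(vol, m))
    subjects[[s]] <- list(subject_id = ids[s], patches = patches)
  }
  g <- gi
  covariates <- data.frame(
    subject_id = ids,
    group = groups,
    age = round(rnorm_clamped(N, config$age_mean[g], config$age_sd[g],
                              55, 95), 1),
    gender = ifelse(stats::runif(N) < config$p_male[g], "M", "F"),
    mmse = round(rnorm_clamped(N, config$mmse_mean[g],
                               config$mmse_sd[g], 0, 30)),
    avlt_ir = round(rnorm_clamped(N, config$avlt$avlt_ir$mean[g],
                                  config$avlt$avlt_ir$sd[g], 0, 15), 1),
    avlt_dr = round(rnorm_clamped(N, config$avlt$avlt_dr$mean[g],
                                  config$avlt$avlt_dr$sd[g], 0, 15), 1),
    avlt_rp = round(rnorm_clamped(N, config$avlt$avlt_rp$mean[g],
                                  config$avlt$avlt_rp$sd[g], 0, 12), 1),
    avlt_rn = round(rnorm_clamped(N, config$avlt$avlt_rn$mean[g],
                                  config$avlt$avlt_rn$sd[g], 0, 12), 1))
  structure(list(subjects = subjects, covariates = covariates,
                 volumes = volumes, masks = masks, config = config),
            class = "cohort")
}

#' Null cohort (no group effect)
#'
#' [make_cohort()] with `effect = 0`: the three groups are exchangeable
#' in their imaging data (covariate and cognition models keep their
#' group structure). Used for type-I-error and permutation calibration.
#'
#' @param n subjects per group (scalar or named vector).
#' @param seed RNG seed.
#' @param ... further arguments to [cohort_config()].
#' @return A `cohort`.
#' @export
null_cohort <- function(n = 10L, seed = 1L, ...) {
  npg <- if (length(n) == 1L) c(NC = n, aMCI = n, AD = n) else n
  make_cohort(cohort_config(n_per_group = npg, effect = 0, seed = seed,
                            ...))
}

#' Separable cohort (extreme group effect)
#'
#' [make_cohort()] with a large effect multiplier: the AD-NC intensity
#' and texture differences dwarf the within-group field variability, so
#' AD vs NC is linearly separable in a handful of features (first-order
#' mean/energy and the coarse-texture GLCM block).
#'
#' @inheritParams null_cohort
#' @param effect effect multiplier (default 5).
#' @return A `cohort`.
#' @export
separable_cohort <- function(n = 8L, seed = 1L, effect = 5, ...) {
  npg <- if (length(n) == 1L) c(NC = n, aMCI = n, AD = n) else n
  make_cohort(cohort_config(n_per_group = npg, effect = effect,
                            seed = seed, ...))
}

#' Write a synthetic cohort to disk
#'
#' Emits per-subject NIfTI volumes, the four shared subregion masks and
#' the manifest CSV in exactly the schema [load_cohort()] reads.
#'
#' @param cohort a `cohort` from [make_cohort()] (must carry `volumes`).
#' @param dir output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"), !is.null(cohort$volumes))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mask_files <- c(mask_lc = "mask_left_caudal.nii.gz",
                  mask_lh = "mask_left_head.nii.gz",
                  mask_rc = "mask_right_caudal.nii.gz",
                  mask_rh = "mask_right_head.nii.gz")
  labs <- names(subregion_codes())
  for (i in seq_along(labs)) {
    RNifti::writeNifti(cohort$masks[[labs[i]]]$data,
                       file.path(dir, mask_files[i]))
  }
  vol_files <- sprintf("vol_%s.nii.gz", cohort$covariates$subject_id)
  for (s in seq_along(cohort$volumes)) {
    RNifti::writeNifti(cohort$volumes[[s]], file.path(dir, vol_files[s]))
  }
  manifest <- cbind(cohort$covariates,
                    vol_path = vol_files,
                    as.data.frame(as.list(mask_files)))
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
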