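## Gray-level run-length matrices and run-emphasis features.
##
## A run is a maximal streak of voxels holding the same gray level along a
## raster line in one of the 13 canonical 3-D directions; runs are broken
## by background voxels and by the patch boundary. Feature values are
## averaged over directions.

#' Compute a directional GLRLM
#'
#' @param qpatch a `quantized_patch`.
#' @param direction integer offset vector (13-direction canonical set).
#' @return Object of class `glrlm`: list with `R` (Ng x Lmax run-count
#'   matrix, Lmax = longest possible run in this direction), `direction`,
#'   `Nr` (total run count), `n_voxels` (foreground voxels traversed).
#' @export
compute_glrlm <- function(qpatch, direction) {
  stopifnot(inherits(qpatch, "quantized_patch"))
  d <- as.integer(direction)
  if (length(d) != 3L || all(d == 0L)) stop("direction must be a nonzero 3-vector")
  lev <- qpatch$levels
  ng <- qpatch$ng
  dims <- dim(lev)
  idx <- arrayInd(seq_along(lev), dims)  # every voxel, background included
  v <- as.vector(lev)
  ## Raster lines: voxels share a line iff their coordinate difference is
  ## parallel to d; two integer forms orthogonal to d identify the line,
  ## the projection onto d orders voxels along it.
  comp <- direction_complement(d)
  key1 <- idx %*% comp[[1]]
  key2 <- idx %*% comp[[2]]
  t_pos <- idx %*% d
  ord <- order(key1, key2, t_pos)
  v <- v[ord]
  step <- sum(d * d)  # t increment between adjacent voxels on a line
  same_line <- c(FALSE, diff(key1[ord]) == 0 & diff(key2[ord]) == 0 &
                          diff(t_pos[ord]) == step)
  ## A new run starts at a line break, a level change, or after background.
  n <- length(v)
  new_run <- !same_line | v != c(0L, v[-n])
  fg <- v > 0L
  run_id <- cumsum(new_run)[fg]
  if (!length(run_id)) {
    return(structure(list(R = matrix(0, ng, 1), direction = d, Nr = 0L,
                          n_voxels = 0L), class = "glrlm"))
  }
  cnt <- tabulate(run_id)
  run_len <- cnt[cnt > 0L]          # run_id non-decreasing: id order ==
  run_lev <- v[fg][!duplicated(run_id)]  # appearance order, so these align
  lmax <- max(run_len)
  R <- matrix(tabulate((run_len - 1L) * ng + run_lev, nbins = ng * lmax),
              ng, lmax)
  structure(list(R = R, direction = d, Nr = length(run_len),
                 n_voxels = sum(fg)),
            class = "glrlm")
}

glrlm_features_one <- function(rlm) {
  R <- rlm$R
  Nr <- rlm$Nr
  Np <- rlm$n_voxels
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  l <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  r_g <- rowSums(R)   # runs per gray level
  r_l <- colSums(R)   # runs per length
  c(short_run_emphasis = sum(R / l^2) / Nr,
    long_run_emphasis  = sum(R * l^2) / Nr,
    gln                = sum(r_g^2) / Nr,
    rln                = sum(r_l^2) / Nr,
    run_percentage     = Nr / Np,
    lglre              = sum(R / g^2) / Nr,
    hglre              = sum(R * g^2) / Nr,
    srlgle             = sum(R / (g^2 * l^2)) / Nr,
    srhgle             = sum(R * g^2 / l^2) / Nr,
    lrlgle             = sum(R * l^2 / g^2) / Nr,
    lrhgle             = sum(R * g^2 * l^2) / Nr)
}

#' GLRLM texture features
#'
#' The 11 run-length features of the GLRLM registry, evaluated per
#' direction and averaged over directions with at least one run.
#'
#' @param qpatch a `quantized_patch`.
#' @param directions list of integer offsets (default: 13 canonical).
#' @return Named numeric vector of length 11, in registry order.
#' @export
glrlm_features <- function(qpatch, directions = glcm_directions()) {
  mats <- lapply(directions, function(d) compute_glrlm(qpatch, d))
  mats <- Filter(function(m) m$Nr > 0L, mats)
  if (!length(mats)) stop("no direction produced a run (empty foreground?)")
  vals <- rowMeans(vapply(mats, glrlm_features_one, numeric(11)))
  stopifnot(identical(names(vals), feature_registry("glrlm")$name))
  vals
}
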