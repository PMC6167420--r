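## Gray-level co-occurrence matrices and Haralick-style features.
##
## Convention: distance d = 1 voxel, the 13 unique 3-D offsets
## (26-connectivity modulo point symmetry); pairs are accumulated
## symmetrically and each directional matrix is normalized on its own;
## features are averaged over the non-empty directions (matrix pooling is
## available via `pool`). Entropies are base 2 with 0 log 0 = 0.

#' Compute a directional GLCM
#'
#' Counts ordered voxel pairs `(v, v + distance * direction)` with both
#' voxels in the foreground, accumulated symmetrically (each pair counted
#' in both orders), then normalized to probabilities.
#'
#' @param qpatch a `quantized_patch`.
#' @param direction integer offset vector, one of the 13 canonical 3-D
#'   offsets (see `glcm_directions`).
#' @param distance pair distance in voxels.
#' @return Object of class `glcm`: list with `P` (Ng x Ng probability
#'   matrix), `direction`, `distance`, `n_pairs` (ordered pair count) and
#'   `empty` (TRUE when no valid pair exists in this direction).
#' @export
compute_glcm <- function(qpatch, direction, distance = 1L) {
  stopifnot(inherits(qpatch, "quantized_patch"))
  direction <- as.integer(direction)
  if (length(direction) != 3L || all(direction == 0L)) {
    stop("direction must be a nonzero 3-vector")
  }
  lev <- qpatch$levels
  ng <- qpatch$ng
  o <- direction * as.integer(distance)
  d <- dim(lev)
  lo <- pmax(1L, 1L - o)
  hi <- pmin(d, d - o)
  P <- matrix(0, ng, ng)
  n_pairs <- 0L
  if (all(lo <= hi)) {
    src <- lev[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dst <- lev[(lo[1] + o[1]):(hi[1] + o[1]),
               (lo[2] + o[2]):(hi[2] + o[2]),
               (lo[3] + o[3]):(hi[3] + o[3]), drop = FALSE]
    keep <- src > 0L & dst > 0L
    if (any(keep)) {
      a <- src[keep]; b <- dst[keep]
      cnt <- matrix(tabulate((a - 1L) * ng + b, nbins = ng * ng),
                    ng, ng, byrow = TRUE)
      cnt <- cnt + t(cnt)
      n_pairs <- sum(cnt)
      P <- cnt / n_pairs
    }
  }
  structure(list(P = P, direction = direction, distance = distance,
                 n_pairs = n_pairs, empty = n_pairs == 0L),
            class = "glcm")
}

## Feature kernel for one normalized co-occurrence matrix.
glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P)
  mu_x <- sum(seq_len(ng) * px)
  mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ## p_{i+j} on k = 2..2Ng and p_{|i-j|} on k = 0..Ng-1
  ksum <- 2:(2 * ng)
  p_sum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  p_diff <- as.vector(rowsum(as.vector(P), as.vector(abs(i - j))))
  kdiff <- 0:(ng - 1)
  sum_avg <- sum(ksum * p_sum)
  HXY <- ent2(P)
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  HXY1 <- -sum(P[pos] * log2(pxy[pos]))
  HXY2 <- ent2(pxy)
  HX <- ent2(px); HY <- ent2(py)
  denom_imc1 <- max(HX, HY)
  mu <- sum(i * P)  # == mu_x by symmetry
  c(autocorrelation     = sum(i * j * P),
    cluster_prominence  = sum((i + j - mu_x - mu_y)^4 * P),
    cluster_shade       = sum((i + j - mu_x - mu_y)^3 * P),
    cluster_tendency    = sum((i + j - mu_x - mu_y)^2 * P),
    contrast            = sum((i - j)^2 * P),
    correlation         = if (sd_x > 0 && sd_y > 0)
                            (sum(i * j * P) - mu_x * mu_y) / (sd_x * sd_y)
                          else 0,
    difference_entropy  = ent2(p_diff),
    dissimilarity       = sum(abs(i - j) * P),
    energy              = sum(P^2),
    entropy             = HXY,
    homogeneity1        = sum(P / (1 + abs(i - j))),
    homogeneity2        = sum(P / (1 + (i - j)^2)),
    imc1                = if (denom_imc1 > 0) (HXY - HXY1) / denom_imc1
                          else 0,
    imc2                = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    idmn                = sum(P / (1 + (i - j)^2 / ng^2)),
    idn                 = sum(P / (1 + abs(i - j) / ng)),
    inverse_variance    = sum(P[i != j] / (i - j)[i != j]^2),
    maximum_probability = max(P),
    sum_average         = sum_avg,
    sum_entropy         = ent2(p_sum),
    sum_variance        = sum((ksum - sum_avg)^2 * p_sum),
    variance            = sum((i - mu)^2 * P))
}

#' GLCM texture features
#'
#' The 22 co-occurrence features of the GLCM registry, computed per
#' direction from that direction's normalized matrix and averaged over
#' the non-empty directions.
#'
#' @param qpatch a `quantized_patch`.
#' @param directions list of integer offsets (default: the 13 canonical
#'   3-D directions).
#' @param distance pair distance in voxels.
#' @param pool if `TRUE`, pool pair counts across directions into a single
#'   matrix before computing features instead of averaging per-direction
#'   features.
#' @return Named numeric vector of length 22, in registry order.
#' @export
glcm_features <- function(qpatch, directions = glcm_directions(),
                          distance = 1L, pool = FALSE) {
  mats <- lapply(directions, function(d)
    compute_glcm(qpatch, d, distance))
  mats <- Filter(function(m) !m$empty, mats)
  if (!length(mats)) stop("no direction produced a valid voxel pair")
  if (pool) {
    cnt <- Reduce(`+`, lapply(mats, function(m) m$P * m$n_pairs))
    vals <- glcm_features_one(cnt / sum(cnt))
  } else {
    per_dir <- vapply(mats, function(m) glcm_features_one(m$P),
                      numeric(22))
    vals <- rowMeans(per_dir)
  }
  stopifnot(identical(names(vals), feature_registry("glcm")$name))
  vals
}
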