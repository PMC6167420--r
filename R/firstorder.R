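## Gray-level quantization and first-order (intensity histogram) features.

#' Quantize a patch to Ng gray levels
#'
#' Discretizes foreground intensities into `ng` equal-width bins spanning
#' the foreground min-max range; the highest bin is closed so the maximum
#' maps to level `ng`. Background voxels hold level 0. Quantization is a
#' prerequisite of the co-occurrence and run-length matrices.
#'
#' @param patch an `roi_patch`.
#' @param ng number of gray levels (>= 2).
#' @return Object of class `quantized_patch`: list with `levels` (integer
#'   array, 1..ng on foreground, 0 on background), `ng`, `bin_edges`
#'   (ng + 1 thresholds).
#' @export
quantize <- function(patch, ng = 64L) {
  stopifnot(inherits(patch, "roi_patch"))
  ng <- as.integer(ng)
  if (ng < 2L) stop("ng must be >= 2")
  fg <- patch_foreground(patch)
  lo <- min(fg); hi <- max(fg)
  if (hi == lo) {
    warning("constant-intensity patch: all foreground voxels map to level 1")
    lev <- patch$mask  # 1 on foreground, 0 on background
    edges <- seq(lo - 0.5, lo + 0.5, length.out = ng + 1L)
  } else {
    edges <- seq(lo, hi, length.out = ng + 1L)
    raw <- floor((patch$values - lo) / (hi - lo) * ng) + 1
    raw <- pmin(pmax(raw, 1), ng)  # closes the top bin
    lev <- as.integer(raw) * patch$mask
  }
  lev <- array(as.integer(lev), dim(patch$values))
  structure(list(levels = lev, ng = ng, bin_edges = edges),
            class = "quantized_patch")
}

## Internal: quantize a bare numeric vector (used for the first-order
## histogram so entropy/uniformity share the run configuration's Ng).
bin_probabilities <- function(x, ng) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(1)
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * ng) + 1, 1), ng)
  p <- tabulate(b, nbins = ng) / length(x)
  p[p > 0]
}

#' First-order intensity features
#'
#' The 14 histogram/statistics features of the intensity registry,
#' computed over foreground voxels only. Entropy and uniformity use an
#' `ng`-bin equal-width histogram over the foreground range; entropy is
#' base 2 with the 0 log 0 = 0 convention. Skewness and kurtosis are the
#' third and fourth standardized moments (kurtosis non-excess, Gaussian
#' -> 3); on a zero-variance patch both are returned as 0 so feature
#' vectors stay finite.
#'
#' @param patch an `roi_patch`.
#' @param ng histogram bin count (shared with the texture quantization).
#' @return Named numeric vector of length 14, in registry order.
#' @export
intensity_features <- function(patch, ng = 64L) {
  x <- patch_foreground(patch)
  n <- length(x)
  mu <- mean(x)
  cent <- x - mu
  v_pop <- mean(cent^2)
  p <- bin_probabilities(x, ng)
  out <- c(
    energy     = sum(x^2),
    entropy    = -sum(p * log2(p)),
    kurtosis   = if (v_pop > 0) mean(cent^4) / v_pop^2 else 0,
    maximum    = max(x),
    mean       = mu,
    mad        = mean(abs(cent)),
    median     = stats::median(x),
    minimum    = min(x),
    range      = max(x) - min(x),
    rms        = sqrt(mean(x^2)),
    skewness   = if (v_pop > 0) mean(cent^3) / v_pop^1.5 else 0,
    sd         = stats::sd(x),
    uniformity = sum(p^2),
    variance   = stats::var(x))
  if (n < 2) out[c("sd", "variance")] <- 0
  out
}
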