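## Single-level separable 3-D discrete wavelet decomposition (Symlet-4,
## periodization boundary) and the companion mask down-sampling.
##
## Periodization keeps the per-axis transform orthogonal for every even
## length, which makes energy conservation and perfect reconstruction
## exactly testable; odd axes are extended by repeating the last sample
## (ceil(n/2) coefficients per axis either way).

## 8-tap Symlet-4 analysis/synthesis filter pair (orthonormal).
sym4_filters <- function() {
  dec_lo <- c(-0.07576571478927333, -0.02963552764599851,
              0.49761866763201545, 0.8037387518059161,
              0.29785779560527736, -0.09921954357684722,
              -0.012603967262037833, 0.0322231006040427)
  ## quadrature mirror: g[m] = (-1)^m h[L-1-m]
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L) - 1)
  list(lo = dec_lo, hi = dec_hi)
}

## Decimated circulant analysis operators for an even signal length n:
## row k of A_lo is dec_lo placed at position 2k (mod n). t(A) is the
## synthesis operator (the stacked matrix is orthogonal for even n).
wavelet_operators <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    stopifnot(n %% 2L == 0L)
    f <- sym4_filters()
    L <- length(f$lo)
    half <- n %/% 2L
    A_lo <- matrix(0, half, n)
    A_hi <- matrix(0, half, n)
    for (k in seq_len(half)) {
      pos <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
      for (m in seq_len(L)) {
        A_lo[k, pos[m]] <- A_lo[k, pos[m]] + f$lo[m]
        A_hi[k, pos[m]] <- A_hi[k, pos[m]] + f$hi[m]
      }
    }
    res <- list(lo = A_lo, hi = A_hi)
    cache[[key]] <- res
    res
  }
})

## Apply f(matrix) -> matrix along one axis of a 3-D array.
apply_axis <- function(a, axis, f) {
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  d <- dim(b)
  m <- f(matrix(b, nrow = d[1]))
  dim(m) <- c(nrow(m), d[2], d[3])
  aperm(m, order(perm))
}

dwt_axis <- function(a, axis) {
  n <- dim(a)[axis]
  if (n < 2L) stop("axis ", axis, " has length ", n, "; need >= 2")
  pad <- n %% 2L == 1L
  op <- wavelet_operators(if (pad) n + 1L else n)
  f_lo <- function(m) {
    if (pad) m <- rbind(m, m[nrow(m), , drop = FALSE])
    op$lo %*% m
  }
  f_hi <- function(m) {
    if (pad) m <- rbind(m, m[nrow(m), , drop = FALSE])
    op$hi %*% m
  }
  list(L = apply_axis(a, axis, f_lo), H = apply_axis(a, axis, f_hi))
}

idwt_axis <- function(lo, hi, axis, n_out) {
  pad <- n_out %% 2L == 1L
  op <- wavelet_operators(if (pad) n_out + 1L else n_out)
  res <- apply_axis(lo, axis, function(m) t(op$lo) %*% m) +
         apply_axis(hi, axis, function(m) t(op$hi) %*% m)
  if (pad) {
    keep <- seq_len(n_out)
    res <- switch(axis,
                  res[keep, , , drop = FALSE],
                  res[, keep, , drop = FALSE],
                  res[, , keep, drop = FALSE])
  }
  res
}

#' Single-level 3-D wavelet decomposition of a patch
#'
#' Separable Symlet-4 decomposition into the eight sub-bands LLL..HHH
#' (letter order = filter applied along axes 1, 2, 3; L = low-pass,
#' H = high-pass), decimated by 2 per axis with periodization boundary.
#' Background voxels are zero-filled before filtering; each band carries
#' the max-pooled companion mask (see [subband_mask()]) so downstream
#' features use foreground coefficients only.
#'
#' @param patch an `roi_patch` (every axis length >= 2), or a bare 3-D
#'   array (then the full grid is foreground).
#' @return Named list of 8 `subband_patch` objects in fixed band order;
#'   each has `values` (coefficient array), `mask`, `band`, `label`,
#'   `n_voxels`.
#' @export
dwt3 <- function(patch) {
  if (inherits(patch, "roi_patch")) {
    x <- patch$values * patch$mask
    mask <- patch$mask
    label <- patch$label
  } else {
    x <- patch
    mask <- array(1L, dim(x))
    label <- NA_character_
  }
  if (any(dim(x) < 2L)) {
    stop("every patch axis must have length >= 2 for the decomposition")
  }
  s1 <- dwt_axis(x, 1L)
  s2 <- lapply(s1, dwt_axis, axis = 2L)
  bands <- list()
  for (b1 in c("L", "H")) for (b2 in c("L", "H")) {
    s3 <- dwt_axis(s2[[b1]][[b2]], 3L)
    for (b3 in c("L", "H")) {
      bands[[paste0(b1, b2, b3)]] <- s3[[b3]]
    }
  }
  bands <- bands[band_codes(include_original = FALSE)]
  pooled <- subband_mask(mask)
  lapply(names(bands), function(code) {
    structure(list(values = bands[[code]], mask = pooled, band = code,
                   label = label, n_voxels = sum(pooled)),
              class = c("subband_patch", "roi_patch"))
  }) |> stats::setNames(names(bands))
}

#' Inverse of [dwt3()]
#'
#' Reconstructs the zero-filled input array from the eight coefficient
#' arrays via the synthesis (transposed) filter bank.
#'
#' @param bands list of 8 sub-band patches (or bare coefficient arrays)
#'   named LLL..HHH.
#' @param dim_out integer vector: the original array dimensions.
#' @return 3-D numeric array of dimension `dim_out`.
#' @export
idwt3 <- function(bands, dim_out) {
  arr <- lapply(bands, function(b) if (is.list(b)) b$values else b)
  rec2 <- list()
  for (b1 in c("L", "H")) for (b2 in c("L", "H")) {
    rec2[[paste0(b1, b2)]] <- idwt_axis(arr[[paste0(b1, b2, "L")]],
                                        arr[[paste0(b1, b2, "H")]],
                                        3L, dim_out[3])
  }
  rec1 <- list()
  for (b1 in c("L", "H")) {
    rec1[[b1]] <- idwt_axis(rec2[[paste0(b1, "L")]],
                            rec2[[paste0(b1, "H")]], 2L, dim_out[2])
  }
  idwt_axis(rec1[["L"]], rec1[["H"]], 1L, dim_out[1])
}

#' Down-sample an ROI mask to the sub-band grid
#'
#' 2x2x2 max-pooling: a sub-band voxel is foreground iff any of its
#' (up to) 8 source voxels is foreground. Matches the ceil(n/2) band
#' shapes of [dwt3()].
#'
#' @param mask 3-D binary array.
#' @return 3-D binary integer array of dimension `ceiling(dim(mask)/2)`.
#' @export
subband_mask <- function(mask) {
  if (sum(mask) == 0L) stop("empty mask")
  out <- mask
  for (axis in 1:3) {
    out <- apply_axis(out, axis, function(m) {
      n <- nrow(m)
      i1 <- seq(1L, n, 2L)
      i2 <- pmin(i1 + 1L, n)
      pmax(m[i1, , drop = FALSE], m[i2, , drop = FALSE])
    })
  }
  pooled <- array(as.integer(out), dim(out))
  if (sum(pooled) == 0L) stop("pooled mask is empty")
  pooled
}
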