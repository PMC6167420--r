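#' @keywords internal
"_PACKAGE"

## Fixed vocabularies defining feature-vector column order. Order is
## load-bearing: tables written by one run must be bit-compatible with
## tables read by another.

#' Hippocampal subregion codes
#'
#' The four regions of interest, in canonical order: left caudal, left head,
#' right caudal, right head.
#'
#' @return Named character vector of short codes (`LC`, `LH`, `RC`, `RH`),
#'   names are the long labels used in manifests.
#' @export
subregion_codes <- function() {
  c(left_caudal = "LC", left_head = "LH",
    right_caudal = "RC", right_head = "RH")
}

#' Wavelet sub-band codes
#'
#' Image channels a feature block can be computed on: the unfiltered image
#' (`orig`) followed by the eight sub-bands of a single-level 3-D wavelet
#' decomposition, each letter marking low- (L) or high-pass (H) filtering
#' along the x, y, z axes in that order.
#'
#' @param include_original include `"orig"` as the first entry.
#' @return Character vector of band codes in fixed order.
#' @export
band_codes <- function(include_original = TRUE) {
  bands <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  if (include_original) c("orig", bands) else bands
}

#' Radiomic feature registry
#'
#' The 47 base features computed per (subregion, band): 14 first-order
#' intensity-histogram features, 22 GLCM (Haralick-style) features and 11
#' GLRLM run-length features, each with a stable short name. Row order is
#' the canonical within-block feature order.
#'
#' @param family optionally restrict to one of `"intensity"`, `"glcm"`,
#'   `"glrlm"`.
#' @return `data.frame` with columns `name`, `family`, `description`.
#' @export
feature_registry <- function(family = NULL) {
  intensity <- c(
    energy      = "sum of squared intensities",
    entropy     = "Shannon entropy (base 2) of the intensity histogram",
    kurtosis    = "fourth standardized moment (non-excess; Gaussian = 3)",
    maximum     = "maximum intensity",
    mean        = "mean intensity",
    mad         = "mean absolute deviation from the mean",
    median      = "median intensity",
    minimum     = "minimum intensity",
    range       = "intensity range",
    rms         = "root mean square intensity",
    skewness    = "third standardized moment",
    sd          = "sample standard deviation",
    uniformity  = "sum of squared histogram probabilities",
    variance    = "sample variance")
  glcm <- c(
    autocorrelation     = "sum_{ij} i*j*p(i,j)",
    cluster_prominence  = "fourth moment about (mu_x + mu_y)",
    cluster_shade       = "third moment about (mu_x + mu_y)",
    cluster_tendency    = "second moment about (mu_x + mu_y)",
    contrast            = "sum_{ij} (i-j)^2 p(i,j)",
    correlation         = "normalized covariance of (i, j)",
    difference_entropy  = "entropy of p_{|i-j|}",
    dissimilarity       = "sum_{ij} |i-j| p(i,j)",
    energy              = "angular second moment, sum p(i,j)^2",
    entropy             = "co-occurrence entropy (base 2)",
    homogeneity1        = "sum p(i,j) / (1 + |i-j|)",
    homogeneity2        = "sum p(i,j) / (1 + (i-j)^2)",
    imc1                = "informational measure of correlation 1",
    imc2                = "informational measure of correlation 2",
    idmn                = "inverse difference moment normalized",
    idn                 = "inverse difference normalized",
    inverse_variance    = "sum_{i!=j} p(i,j) / (i-j)^2",
    maximum_probability = "max p(i,j)",
    sum_average         = "mean of p_{i+j}",
    sum_entropy         = "entropy of p_{i+j}",
    sum_variance        = "variance of p_{i+j} about the sum average",
    variance            = "sum (i - mu)^2 p(i,j)")
  glrlm <- c(
    short_run_emphasis      = "sum R(g,l)/l^2 / Nr",
    long_run_emphasis       = "sum R(g,l)*l^2 / Nr",
    gln                     = "gray level non-uniformity",
    rln                     = "run length non-uniformity",
    run_percentage          = "Nr / number of foreground voxels",
    lglre                   = "low gray level run emphasis",
    hglre                   = "high gray level run emphasis",
    srlgle                  = "short run low gray level emphasis",
    srhgle                  = "short run high gray level emphasis",
    lrlgle                  = "long run low gray level emphasis",
    lrhgle                  = "long run high gray level emphasis")
  reg <- rbind(
    data.frame(name = names(intensity), family = "intensity",
               description = unname(intensity)),
    data.frame(name = names(glcm), family = "glcm",
               description = unname(glcm)),
    data.frame(name = names(glrlm), family = "glrlm",
               description = unname(glrlm)))
  rownames(reg) <- NULL
  if (!is.null(family)) {
    family <- match.arg(family, c("intensity", "glcm", "glrlm"))
    reg <- reg[reg$family == family, , drop = FALSE]
    rownames(reg) <- NULL
  }
  reg
}

#' Feature-vector column names
#'
#' Deterministic product-order column vocabulary:
#' subregion (LC, LH, RC, RH) x band (orig, LLL..HHH) x registry order,
#' written as `<subregion>__<band>__<family>__<feature>`.
#'
#' @param per_subject if `TRUE` (default) all 1692 per-subject columns;
#'   if `FALSE` the 423 per-subregion names without the subregion prefix.
#' @return Character vector of length 1692 (or 423).
#' @export
feature_column_names <- function(per_subject = TRUE) {
  reg <- feature_registry()
  per_band <- paste(reg$family, reg$name, sep = "__")
  per_region <- as.vector(vapply(
    band_codes(), function(b) paste(b, per_band, sep = "__"),
    character(nrow(reg))))
  if (!per_subject) return(per_region)
  as.vector(vapply(
    unname(subregion_codes()),
    function(s) paste(s, per_region, sep = "__"),
    character(length(per_region))))
}

#' Parse feature-column names
#'
#' Inverse of the naming grammar used by [feature_column_names()].
#'
#' @param x character vector of column names.
#' @return `data.frame` with columns `subregion`, `band`, `family`,
#'   `feature`, `base` (the subregion-free `band__family__feature`
#'   identity used for multi-region bookkeeping).
#' @export
parse_feature_name <- function(x) {
  parts <- strsplit(x, "__", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed feature column name(s): ",
         paste(utils::head(x[bad], 3), collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(subregion = m[, 1], band = m[, 2], family = m[, 3],
             feature = m[, 4],
             base = paste(m[, 2], m[, 3], m[, 4], sep = "__"))
}

## 13 canonical 3-D offsets: the 26-neighborhood modulo point symmetry.
glcm_directions <- function() {
  list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
       c(1L, 1L, 0L), c(1L, -1L, 0L),
       c(1L, 0L, 1L), c(1L, 0L, -1L),
       c(0L, 1L, 1L), c(0L, 1L, -1L),
       c(1L, 1L, 1L), c(1L, -1L, 1L), c(1L, 1L, -1L), c(1L, -1L, -1L))
}

## Two integer vectors orthogonal to d spanning its complement; identifies
## the raster line a voxel lies on for run-length traversal.
direction_complement <- function(d) {
  cand <- list(c(d[2], -d[1], 0L), c(d[3], 0L, -d[1]), c(0L, d[3], -d[2]))
  keep <- Filter(function(v) any(v != 0L), cand)
  for (i in seq_along(keep)) {
    for (j in seq_along(keep)) {
      if (i >= j) next
      a <- keep[[i]]; b <- keep[[j]]
      cr <- c(a[2] * b[3] - a[3] * b[2],
              a[3] * b[1] - a[1] * b[3],
              a[1] * b[2] - a[2] * b[1])
      if (any(cr != 0L)) return(list(a, b))
    }
  }
  stop("degenerate direction")  # unreachable for nonzero d
}
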