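## Assembly of per-subregion (423) and per-subject (1692) feature vectors
## and the feature-table CSV round trip.

#' Radiomics run configuration
#'
#' @param ng gray levels for quantization and first-order histograms.
#' @param distance GLCM pair distance in voxels.
#' @param pool_glcm pool directional GLCM counts instead of averaging
#'   per-direction features.
#' @param excess_kurtosis report kurtosis as excess (Gaussian -> 0)
#'   instead of the default non-excess convention (Gaussian -> 3).
#' @return list of class `radiomics_config`.
#' @export
radiomics_config <- function(ng = 64L, distance = 1L, pool_glcm = FALSE,
                             excess_kurtosis = FALSE) {
  stopifnot(ng >= 2L, distance >= 1L)
  structure(list(ng = as.integer(ng), distance = as.integer(distance),
                 pool_glcm = isTRUE(pool_glcm),
                 excess_kurtosis = isTRUE(excess_kurtosis)),
            class = "radiomics_config")
}

## 47 base features of one (already cropped, masked) patch.
base_features <- function(patch, config) {
  fo <- intensity_features(patch, ng = config$ng)
  if (config$excess_kurtosis && fo[["sd"]] > 0) {
    fo[["kurtosis"]] <- fo[["kurtosis"]] - 3
  }
  qp <- suppressWarnings(quantize(patch, config$ng))
  c(fo,
    glcm_features(qp, distance = config$distance, pool = config$pool_glcm),
    glrlm_features(qp))
}

#' Extract the 423 features of one subregion
#'
#' 47 base features (14 first-order + 22 GLCM + 11 GLRLM) on the original
#' patch, then on each of the 8 wavelet sub-bands, concatenated in fixed
#' band order. Sub-band quantization is re-derived per band from that
#' band's own coefficient range (wavelet coefficients are signed; a global
#' intensity range is meaningless across bands).
#'
#' @param patch an `roi_patch`.
#' @param config a [radiomics_config()].
#' @return Named numeric vector of length 423 (names are the
#'   subregion-free `band__family__feature` grammar).
#' @export
extract_subregion_features <- function(patch,
                                       config = radiomics_config()) {
  stopifnot(inherits(patch, "roi_patch"))
  bands <- dwt3(patch)
  blocks <- c(list(orig = base_features(patch, config)),
              lapply(bands, base_features, config = config))
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- feature_column_names(per_subject = FALSE)
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite feature value(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Extract the 1692 features of one subject
#'
#' Concatenates the four subregion vectors in canonical subregion order
#' (LC, LH, RC, RH), regardless of the order patches are supplied in.
#'
#' @param patches list of 4 `roi_patch`, one per subregion label.
#' @param config a [radiomics_config()].
#' @return Named numeric vector of length 1692.
#' @export
extract_subject_features <- function(patches,
                                     config = radiomics_config()) {
  labels <- vapply(patches, function(p) p$label, character(1))
  want <- names(subregion_codes())
  if (anyDuplicated(labels)) stop("duplicate subregion label in patches")
  miss <- setdiff(want, labels)
  if (length(miss)) stop("missing subregion patch(es): ",
                         paste(miss, collapse = ", "))
  ordered <- patches[match(want, labels)]
  out <- unlist(lapply(ordered, extract_subregion_features,
                       config = config), use.names = FALSE)
  names(out) <- feature_column_names(per_subject = TRUE)
  out
}

#' Extract the feature table of a cohort
#'
#' @param cohort a `cohort` (see [load_cohort()] or [make_cohort()]).
#' @param config a [radiomics_config()].
#' @param verbose print per-subject progress.
#' @return Object of class `feature_table`: list with `features`
#'   (subjects x 1692 numeric matrix, rownames = subject ids) and
#'   `covariates` (data.frame in the same row order).
#' @export
extract_cohort_features <- function(cohort, config = radiomics_config(),
                                    verbose = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    if (verbose) message("extracting features: ", s$subject_id)
    extract_subject_features(s$patches, config)
  })
  features <- do.call(rbind, rows)
  rownames(features) <- vapply(cohort$subjects, function(s)
    as.character(s$subject_id), character(1))
  feature_table(features, cohort$covariates)
}

#' Construct a feature table
#'
#' @param features numeric matrix, subjects x 1692, columns named by the
#'   [feature_column_names()] grammar.
#' @param covariates data.frame with `subject_id`, `group`, `age`,
#'   `gender`, `mmse` (AVLT columns optional), same row order.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(features, covariates) {
  want <- feature_column_names()
  if (is.null(colnames(features))) colnames(features) <- want
  if (ncol(features) != length(want) ||
      !identical(colnames(features), want)) {
    stop("feature matrix must have exactly ", length(want),
         " columns in canonical order")
  }
  if (nrow(features) != nrow(covariates)) {
    stop("feature rows (", nrow(features), ") and covariate rows (",
         nrow(covariates), ") differ")
  }
  if (nrow(features) && any(!is.finite(features))) {
    stop("feature table contains non-finite cells")
  }
  structure(list(features = features, covariates = covariates),
            class = "feature_table")
}

#' Write / read a feature table
#'
#' Two CSVs sharing `subject_id`: `<stem>_features.csv` (full decimal
#' precision, 17 significant digits) and `<stem>_covariates.csv`. The
#' round trip is lossless to floating-point resolution.
#'
#' @param table a `feature_table`.
#' @param stem output path stem.
#' @return `write_feature_table`: the two paths, invisibly.
#' @export
write_feature_table <- function(table, stem) {
  stopifnot(inherits(table, "feature_table"))
  fpath <- paste0(stem, "_features.csv")
  cpath <- paste0(stem, "_covariates.csv")
  df <- data.frame(subject_id = rownames(table$features),
                   signif(table$features, 17), check.names = FALSE)
  ## format() through write.csv would round; print full precision
  old <- options(digits = 17, scipen = 0)
  on.exit(options(old))
  utils::write.csv(df, fpath, row.names = FALSE)
  utils::write.csv(table$covariates, cpath, row.names = FALSE)
  invisible(c(features = fpath, covariates = cpath))
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(stem) {
  fpath <- paste0(stem, "_features.csv")
  cpath <- paste0(stem, "_covariates.csv")
  for (p in c(fpath, cpath)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  df <- utils::read.csv(fpath, check.names = FALSE)
  cov <- utils::read.csv(cpath)
  want <- feature_column_names()
  got <- setdiff(names(df), "subject_id")
  if (length(got) != length(want) || !identical(got, want)) {
    stop("feature file has ", length(got),
         " feature columns; expected the canonical ", length(want))
  }
  m <- as.matrix(df[, want, drop = FALSE])
  rownames(m) <- df$subject_id
  feature_table(m, cov)
}
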