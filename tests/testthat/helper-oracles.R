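## Fixture builders and independent brute-force oracles. The oracles are
## deliberately naive (explicit loops, direct formulas) and share no code
## with the package internals they check.

## Direct construction of a patch / quantized patch, bypassing I/O.
patch_of <- function(values, mask = NULL, label = "left_caudal") {
  values <- as.array(values)
  if (length(dim(values)) < 3L) {
    dim(values) <- c(dim(values), rep(1L, 3L - length(dim(values))))
  }
  if (is.null(mask)) mask <- array(1L, dim(values))
  structure(list(values = values, mask = array(as.integer(mask),
                                               dim(values)),
                 label = label, n_voxels = sum(mask)),
            class = "roi_patch")
}

qpatch_of <- function(levels, ng = max(levels)) {
  levels <- as.array(levels)
  if (length(dim(levels)) < 3L) {
    dim(levels) <- c(dim(levels), rep(1L, 3L - length(dim(levels))))
  }
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 ng = as.integer(ng),
                 bin_edges = seq(0.5, ng + 0.5, length.out = ng + 1)),
            class = "quantized_patch")
}

random_patch <- function(seed, dims = c(5L, 5L, 5L), p_fg = 0.8) {
  set.seed(seed)
  vals <- array(stats::rnorm(prod(dims)), dims)
  repeat {
    mask <- array(as.integer(stats::runif(prod(dims)) < p_fg), dims)
    if (sum(mask) >= 2L) break
  }
  patch_of(vals, mask)
}

random_qpatch <- function(seed, dims = c(4L, 4L, 4L), ng = 4L,
                          p_fg = 0.8) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  mask <- array(as.integer(stats::runif(prod(dims)) < p_fg), dims)
  qpatch_of(lev * mask, ng)
}

## Exhaustive ordered-pair enumeration GLCM oracle.
glcm_oracle <- function(levels, ng, direction, distance = 1L) {
  d <- dim(levels)
  o <- direction * distance
  cnt <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      w <- c(i, j, k) + o
      if (any(w < 1L) || any(w > d)) next
      a <- levels[i, j, k]; b <- levels[w[1], w[2], w[3]]
      if (a > 0L && b > 0L) {
        cnt[a, b] <- cnt[a, b] + 1
        cnt[b, a] <- cnt[b, a] + 1
      }
    }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

## Walk-every-line run-enumeration GLRLM oracle.
glrlm_oracle <- function(levels, ng, direction) {
  d <- dim(levels)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    for (k in seq_len(d[3])) {
      v <- c(i, j, k)
      prev <- v - direction
      if (all(prev >= 1L) && all(prev <= d)) next  # not a line start
      line <- integer(0)
      w <- v
      while (all(w >= 1L) && all(w <= d)) {
        line <- c(line, levels[w[1], w[2], w[3]])
        w <- w + direction
      }
      r <- rle(line)
      keep <- r$values > 0L
      if (any(keep)) {
        runs[[length(runs) + 1L]] <- cbind(level = r$values[keep],
                                           len = r$lengths[keep])
      }
    }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(list(R = matrix(0, ng, 1), Nr = 0L))
  R <- matrix(0, ng, max(runs[, "len"]))
  for (q in seq_len(nrow(runs))) {
    R[runs[q, "level"], runs[q, "len"]] <-
      R[runs[q, "level"], runs[q, "len"]] + 1
  }
  list(R = R, Nr = nrow(runs))
}

## Exhaustive pair-counting AUC oracle.
auc_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

## Direct-formula one-way F oracle.
oneway_f_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- nlevels(groups); N <- length(values)
  (ssb / (k - 1)) / (ssw / (N - k))
}

## Direct-formula Welch T oracle (printed-formula form).
welch_t_oracle <- function(x1, x2) {
  (mean(x1) - mean(x2)) /
    sqrt(var(x1) / length(x1) + var(x2) / length(x2))
}

## Rank-based Spearman oracle (midranks, Pearson on ranks).
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## A feature table with canonical column names from a bare matrix
## (feature-level fixtures for the screening and CV stages).
synthetic_feature_table <- function(features, groups, seed = NULL,
                                    mmse = NULL) {
  n <- nrow(features)
  colnames(features) <- feature_column_names()[seq_len(ncol(features))]
  if (ncol(features) < 1692) {
    pad <- matrix(0, n, 1692 - ncol(features))
    features <- cbind(features, pad)
    colnames(features) <- feature_column_names()
  }
  if (is.null(mmse)) mmse <- round(runif(n, 10, 30))
  cov <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                    group = groups,
                    age = round(runif(n, 60, 80), 1),
                    gender = sample(c("M", "F"), n, replace = TRUE),
                    mmse = mmse)
  feature_table(features, cov)
}

## Gaussian null feature matrix with canonical 1692 columns.
null_feature_matrix <- function(n, p = 1692L) {
  m <- matrix(stats::rnorm(n * p), n, p)
  colnames(m) <- feature_column_names()[seq_len(p)]
  m
}
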