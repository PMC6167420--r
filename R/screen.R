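## Mass-univariate screening: covariate adjustment, one-way ANOVA with
## Bonferroni control, post hoc pairwise Welch tests, Spearman
## correlation with cognitive scores, multi-region bookkeeping.
##
## All tests are vectorized over the 1692 feature columns; base R
## aov/t.test/cor.test on single columns are the reference they are
## checked against in the test suite.

PVAL_FLOOR <- 1e-300  # keeps -log10(P) finite for heat-map output

#' Adjust features for age and gender
#'
#' Per feature, ordinary least squares of the feature on
#' `[1, age, gender]` over all subjects jointly (per-group fitting would
#' absorb the group differences the screen is looking for); the adjusted
#' value is the residual plus the feature's grand mean. A constant
#' covariate column is dropped with a warning.
#'
#' @param table a `feature_table`.
#' @return Object of class `adjusted_table`: list with `features`
#'   (adjusted matrix, same shape), `coefficients` (nuisance fits per
#'   feature), `covariates` (the untouched covariate data.frame).
#' @export
adjust_covariates <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  cov <- table$covariates
  Y <- table$features
  age <- as.numeric(cov$age)
  gender <- cov$gender
  if (!is.numeric(gender)) {
    gender <- as.numeric(factor(gender)) - 1
  }
  X <- cbind(intercept = 1, age = age, gender = gender)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(v)
    stats::var(v) > 0))
  if (!all(keep)) {
    warning("constant covariate column(s) dropped: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- stats::lm.fit(X, Y)
  B <- fit$coefficients
  resid <- Y - X %*% B
  adjusted <- sweep(resid, 2, colMeans(Y), `+`)
  structure(list(features = adjusted, coefficients = t(B),
                 covariates = cov),
            class = "adjusted_table")
}

group_indices <- function(groups) {
  g <- factor(groups)
  if (any(table(g) < 2)) {
    stop("every group needs at least 2 subjects; got counts ",
         paste(table(g), collapse = "/"))
  }
  g
}

## Vectorized one-way fixed-effects F over feature columns.
oneway_f <- function(Y, g) {
  g <- group_indices(g)
  N <- nrow(Y); k <- nlevels(g)
  n_g <- as.vector(table(g))
  gm <- rowsum(Y, g) / n_g                # group means, k x p
  grand <- colMeans(Y)
  ssb <- colSums(n_g * sweep(gm, 2, grand)^2)
  sst <- colSums(sweep(Y, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  F[ssw == 0 & ssb == 0] <- 0            # identical values everywhere
  F[ssw == 0 & ssb > 0] <- Inf
  P <- stats::pf(F, k - 1, N - k, lower.tail = FALSE)
  P[sst == 0] <- 1
  list(F = F, P = P)
}

## Vectorized Welch two-sample t over feature columns.
welch_pair <- function(Y1, Y2) {
  n1 <- nrow(Y1); n2 <- nrow(Y2)
  m1 <- colMeans(Y1); m2 <- colMeans(Y2)
  v1 <- apply(Y1, 2, stats::var); v2 <- apply(Y2, 2, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero <- se2 == 0
  t[zero] <- ifelse(m1[zero] == m2[zero], 0, Inf * sign((m1 - m2)[zero]))
  df[zero] <- n1 + n2 - 2
  P <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  list(t = t, df = df, P = P)
}

#' Mass-univariate ANOVA screen
#'
#' Classical one-way fixed-effects F per feature on the adjusted table,
#' flagged at the Bonferroni-corrected threshold `alpha / n_features`
#' (default 0.01 / 1692). `neg_log10_p` is floored at 1e-300 for finite
#' heat-map output.
#'
#' @param adjusted an `adjusted_table` (or `feature_table`).
#' @param groups group labels per subject (default: the covariate
#'   `group` column).
#' @param alpha family-wise level before correction.
#' @return Object of class `screen_result`: data.frame with one row per
#'   feature column (`column`, `subregion`, `band`, `family`, `feature`,
#'   `base`, `F`, `p_anova`, `neg_log10_p`, `sig_anova`), plus attributes
#'   `alpha`, `threshold`, `groups`.
#' @export
anova_screen <- function(adjusted, groups = NULL, alpha = 0.01) {
  Y <- adjusted$features
  if (is.null(groups)) groups <- adjusted$covariates$group
  res <- oneway_f(Y, groups)
  threshold <- alpha / ncol(Y)
  info <- parse_feature_name(colnames(Y))
  out <- data.frame(column = colnames(Y), info,
                    F = res$F, p_anova = res$P,
                    neg_log10_p = -log10(pmax(res$P, PVAL_FLOOR)),
                    sig_anova = res$P < threshold)
  rownames(out) <- NULL
  structure(out, alpha = alpha, threshold = threshold,
            groups = as.character(groups),
            class = c("screen_result", "data.frame"))
}

#' Post hoc pairwise tests
#'
#' Welch (unequal-variance) two-sample t tests for each group pair
#' (pooled-variance t via `variant = "pooled"`), reported for every
#' feature; the pairwise significance flags are confined to features
#' whose omnibus ANOVA was significant, at the same corrected threshold.
#'
#' @param screen a `screen_result` from [anova_screen()].
#' @param adjusted the `adjusted_table` the screen was run on.
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return The screen data.frame extended with, per pair `ab` in
#'   (`amci_nc`, `ad_nc`, `ad_amci`): `t_<ab>`, `p_<ab>`, `sig_<ab>`.
#' @export
posthoc_pairwise <- function(screen, adjusted, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  Y <- adjusted$features
  groups <- attr(screen, "groups")
  threshold <- attr(screen, "threshold")
  pairs <- list(amci_nc = c("aMCI", "NC"),
                ad_nc = c("AD", "NC"),
                ad_amci = c("AD", "aMCI"))
  for (nm in names(pairs)) {
    pr <- pairs[[nm]]
    Y1 <- Y[groups == pr[1], , drop = FALSE]
    Y2 <- Y[groups == pr[2], , drop = FALSE]
    if (variant == "welch") {
      res <- welch_pair(Y1, Y2)
    } else {
      n1 <- nrow(Y1); n2 <- nrow(Y2)
      v1 <- apply(Y1, 2, stats::var); v2 <- apply(Y2, 2, stats::var)
      sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      t <- (colMeans(Y1) - colMeans(Y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
      t[!is.finite(t)] <- 0
      res <- list(t = t, P = 2 * stats::pt(abs(t), n1 + n2 - 2,
                                           lower.tail = FALSE))
    }
    screen[[paste0("t_", nm)]] <- res$t
    screen[[paste0("p_", nm)]] <- res$P
    screen[[paste0("sig_", nm)]] <- screen$sig_anova & res$P < threshold
  }
  screen
}

#' Spearman correlation screen against a cognitive score
#'
#' Rank correlation (midrank ties) of each adjusted feature with a score
#' over a subject subset — by default the pooled AD + aMCI patients, the
#' subset in which cognition-texture coupling is interpretable. P values
#' use the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param adjusted an `adjusted_table`.
#' @param score numeric vector over all subjects (e.g. MMSE), or the name
#'   of a covariate column.
#' @param subset logical/index vector of subjects, or a character vector
#'   of group labels to pool (default `c("AD", "aMCI")`).
#' @param alpha per-feature significance level (0.01 for MMSE in the
#'   screening protocol, 0.05 for the AVLT maps).
#' @return data.frame: `column`, `rho`, `p_spearman`, `sig_spearman`.
#' @export
spearman_screen <- function(adjusted, score = "mmse",
                            subset = c("AD", "aMCI"), alpha = 0.01) {
  Y <- adjusted$features
  cov <- adjusted$covariates
  if (is.character(score) && length(score) == 1L) {
    if (!score %in% names(cov)) stop("no covariate column '", score, "'")
    score <- cov[[score]]
  }
  if (is.character(subset)) subset <- cov$group %in% subset
  Ys <- Y[subset, , drop = FALSE]
  s <- score[subset]
  n <- nrow(Ys)
  if (n < 5) stop("fewer than 5 subjects in subset")
  if (anyNA(s)) stop("score contains missing values in the subset")
  rs <- rank(s)
  R <- apply(Ys, 2, rank)
  rs_c <- rs - mean(rs)
  R_c <- sweep(R, 2, colMeans(R))
  denom <- sqrt(colSums(R_c^2) * sum(rs_c^2))
  rho <- as.vector(crossprod(R_c, rs_c)) / denom
  rho[denom == 0] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  t <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  P <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  data.frame(column = colnames(Y), rho = rho, p_spearman = P,
             sig_spearman = P < alpha)
}

#' Multi-region significance summary
#'
#' Groups significance flags by base feature identity
#' (`band__family__feature`) across the four subregions and counts base
#' features significant in more than one subregion.
#'
#' @param screen a `screen_result` (any data.frame with `base`,
#'   `subregion` and a logical flag column).
#' @param flag name of the flag column (default `sig_anova`).
#' @return list with `per_subregion` (named flag counts), `per_base`
#'   (data.frame `base`, `n_subregions`, `subregions`), and
#'   `n_multi_region` (count of base features flagged in > 1 subregion).
#' @export
summarize_multiregion <- function(screen, flag = "sig_anova") {
  stopifnot(flag %in% names(screen))
  hits <- screen[screen[[flag]], c("base", "subregion")]
  per_sub <- table(factor(hits$subregion,
                          levels = unname(subregion_codes())))
  if (nrow(hits)) {
    agg <- stats::aggregate(subregion ~ base, data = hits, FUN = function(s)
      paste(sort(unique(s)), collapse = ","))
    agg$n_subregions <- lengths(strsplit(agg$subregion, ","))
    per_base <- data.frame(base = agg$base,
                           n_subregions = agg$n_subregions,
                           subregions = agg$subregion)
  } else {
    per_base <- data.frame(base = character(), n_subregions = integer(),
                           subregions = character())
  }
  list(per_subregion = c(per_sub),
       per_base = per_base,
       n_multi_region = sum(per_base$n_subregions > 1))
}

#' Heat-map matrix of -log10 P values
#'
#' Reshapes a screen result into a (base feature x subregion) matrix of
#' `-log10(P)` for heat-map display.
#'
#' @param screen a `screen_result`.
#' @param p_column which P column to map (default `p_anova`).
#' @return numeric matrix, 423 base features x 4 subregions.
#' @export
neglogp_matrix <- function(screen, p_column = "p_anova") {
  stopifnot(p_column %in% names(screen))
  subs <- unname(subregion_codes())
  bases <- unique(screen$base)
  m <- matrix(NA_real_, length(bases), length(subs),
              dimnames = list(bases, subs))
  m[cbind(match(screen$base, bases), match(screen$subregion, subs))] <-
    -log10(pmax(screen[[p_column]], PVAL_FLOOR))
  m
}
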