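make_adjusted <- function(features, groups, ...) {
  adjust_covariates(synthetic_feature_table(features, groups, ...))
}

test_that("covariate adjustment removes age/gender structure and is
           idempotent", {
  set.seed(41)
  n <- 200L
  age <- runif(n, 55, 85)
  gender <- sample(c("M", "F"), n, replace = TRUE)
  g01 <- as.numeric(factor(gender)) - 1
  groups <- sample(c("NC", "aMCI", "AD"), n, replace = TRUE)
  m <- null_feature_matrix(n, 40L)
  m[, 1] <- 3 * age            # exactly linear in age, no noise
  m[, 2] <- m[, 2] + 5 * g01   # gender offset
  ft <- synthetic_feature_table(m, groups)
  ft$covariates$age <- age
  ft$covariates$gender <- gender
  adj <- adjust_covariates(ft)

  ## perfect fit: residual variance 0 for the age-linear feature
  expect_lt(var(adj$features[, 1]), 1e-18 * var(m[, 1]))
  ## residuals orthogonal to nuisance regressors
  centered <- scale(adj$features[, 1:40], scale = FALSE)
  expect_lt(max(abs(crossprod(centered, age - mean(age)))) / n, 1e-8)
  expect_lt(max(abs(crossprod(centered, g01 - mean(g01)))) / n, 1e-8)

  ## OLS oracle via normal equations on a noise feature
  X <- cbind(1, age, g01)
  beta_oracle <- solve(t(X) %*% X, t(X) %*% m[, 5])
  expect_equal(unname(adj$coefficients[5, ]),
               as.vector(beta_oracle), tolerance = 1e-8)
  ## independent feature: slopes within 3 SE of zero
  fit <- summary(lm(m[, 5] ~ age + g01))
  expect_lt(abs(fit$coefficients["age", "t value"]), 3)

  ## adjusting twice changes nothing
  adj2 <- adjust_covariates(
    feature_table(adj$features, ft$covariates))
  expect_equal(adj2$features, adj$features, tolerance = 1e-10)

  ## constant covariate dropped with warning
  ft$covariates$gender <- "M"
  expect_warning(adjust_covariates(ft), "gender")
})

test_that("the mass-univariate F equals brute-force sums of squares and
           base R aov", {
  set.seed(43)
  groups <- rep(c("NC", "aMCI", "AD"), each = 3)
  m <- null_feature_matrix(9L, 10L)
  adj <- make_adjusted(m, groups)
  scr <- anova_screen(adj)
  for (j in 1:10) {
    y <- adj$features[, j]
    expect_equal(scr$F[j], oneway_f_oracle(y, groups),
                 tolerance = 1e-10)
    ## independent route: base R aov
    a <- summary(aov(y ~ factor(groups)))[[1]]
    expect_equal(scr$F[j], a[["F value"]][1], tolerance = 1e-8)
    expect_equal(scr$p_anova[j], a[["Pr(>F)"]][1], tolerance = 1e-8)
  }
  expect_identical(attr(scr, "threshold"), 0.01 / 1692)

  ## identical values in and across groups: F = 0, P = 1
  m2 <- matrix(5, 9, 1692,
               dimnames = list(NULL, feature_column_names()))
  adj2 <- make_adjusted(m2, groups)
  scr2 <- anova_screen(adj2)
  expect_true(all(scr2$F == 0))
  expect_true(all(scr2$p_anova == 1))
  expect_false(any(scr2$sig_anova))
})

test_that("post hoc Welch t matches t.test and orders by planted effect", {
  set.seed(45)
  groups <- rep(c("NC", "aMCI", "AD"), times = c(8, 7, 9))
  m <- null_feature_matrix(24L, 8L)
  adj <- make_adjusted(m, groups)
  scr <- posthoc_pairwise(anova_screen(adj), adj)
  for (j in 1:8) {
    y <- adj$features[, j]
    tt <- t.test(y[groups == "AD"], y[groups == "NC"])
    expect_equal(scr$t_ad_nc[j], unname(tt$statistic),
                 tolerance = 1e-8)
    expect_equal(scr$p_ad_nc[j], tt$p.value, tolerance = 1e-8)
    ## pooled variant against var.equal t.test
    tp <- t.test(y[groups == "aMCI"], y[groups == "NC"],
                 var.equal = TRUE)
    scr_p <- posthoc_pairwise(anova_screen(adj), adj,
                              variant = "pooled")
    expect_equal(scr_p$t_amci_nc[j], unname(tp$statistic),
                 tolerance = 1e-8)
  }
  ## identical groups: no flags
  expect_false(any(scr$sig_ad_nc | scr$sig_amci_nc | scr$sig_ad_amci))

  ## monotone planted effect: AD-NC is the most significant pair in the
  ## large majority of replicates
  hits <- 0L
  for (rep in 1:40) {
    y <- rnorm(24) + c(NC = 0, aMCI = 1.25, AD = 2.5)[groups]
    adj1 <- make_adjusted(matrix(y, 24, 1), groups)
    s1 <- posthoc_pairwise(anova_screen(adj1), adj1)
    if (s1$p_ad_nc[1] <= s1$p_amci_nc[1] &&
        s1$p_ad_nc[1] <= s1$p_ad_amci[1]) hits <- hits + 1L
  }
  expect_gte(hits / 40, 0.95)
})

test_that("Spearman screening equals the rank-correlation oracle and
           flags monotone features", {
  set.seed(47)
  groups <- rep(c("NC", "aMCI", "AD"), times = c(4, 5, 5))
  m <- null_feature_matrix(14L, 6L)
  mmse <- sample(5:30, 14)          # distinct scores (no midrank ties)
  m[, 3] <- order(order(mmse)) * 2  # strictly monotone in the score
  adj <- make_adjusted(m, groups, mmse = mmse)
  ## skip adjustment noise for the monotone check: use raw features
  raw <- structure(list(features = m, covariates = adj$covariates),
                   class = "adjusted_table")
  sp <- spearman_screen(raw, score = "mmse", subset = c("AD", "aMCI"))
  sub <- adj$covariates$group %in% c("AD", "aMCI")
  expect_equal(sp$rho[3], 1)
  for (j in 1:6) {
    oracle <- spearman_oracle(m[sub, j], mmse[sub])
    expect_equal(sp$rho[j], oracle, tolerance = 1e-12)
    ## independent route: base R cor
    expect_equal(sp$rho[j],
                 cor(m[sub, j], mmse[sub], method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman_screen(raw, score = "mmse",
                               subset = rep(FALSE, 14)), "fewer than 5")
})

test_that("multi-region summary counts base features across subregions", {
  set.seed(49)
  groups <- rep(c("NC", "aMCI", "AD"), each = 4)
  adj <- make_adjusted(null_feature_matrix(12L), groups)
  scr <- anova_screen(adj)

  ## plant flags: one base feature in LC and RC, another in LH only
  scr$sig_anova <- FALSE
  base1 <- scr$base[scr$subregion == "LC"][5]
  scr$sig_anova[scr$base == base1 &
                  scr$subregion %in% c("LC", "RC")] <- TRUE
  base2 <- scr$base[scr$subregion == "LH"][9]
  scr$sig_anova[scr$base == base2 & scr$subregion == "LH"] <- TRUE
  s <- summarize_multiregion(scr)
  expect_identical(s$n_multi_region, 1L)
  expect_identical(unname(s$per_subregion[c("LC", "LH", "RC", "RH")]),
                   c(1L, 1L, 1L, 0L))

  ## no flags
  scr$sig_anova <- FALSE
  expect_identical(summarize_multiregion(scr)$n_multi_region, 0L)

  ## randomized flag sets vs set-intersection oracle
  for (seed in 1:10) {
    set.seed(seed)
    scr$sig_anova <- runif(nrow(scr)) < 0.01
    s <- summarize_multiregion(scr)
    hits <- scr[scr$sig_anova, ]
    oracle <- sum(vapply(split(hits$subregion, hits$base),
                         function(x) length(unique(x)) > 1, logical(1)))
    expect_identical(s$n_multi_region, as.integer(oracle))
  }

  ## heat-map matrix dimensions and values
  hm <- neglogp_matrix(anova_screen(adj))
  expect_identical(dim(hm), c(423L, 4L))
  expect_true(all(is.finite(hm)))
})

test_that("screening is invariant to row/column order and Bonferroni
           flags are monotone in alpha", {
  set.seed(51)
  groups <- rep(c("NC", "aMCI", "AD"), times = c(5, 4, 5))
  m <- null_feature_matrix(14L)
  m[, 1:20] <- m[, 1:20] + 2 * (groups == "AD")  # some real signal
  adj <- make_adjusted(m, groups)
  scr <- anova_screen(adj)

  perm <- sample(14)
  ft2 <- synthetic_feature_table(m[perm, ], groups[perm])
  ft2$covariates <- adj$covariates[perm, ]
  scr2 <- anova_screen(adjust_covariates(ft2))
  expect_equal(scr2$F, scr$F, tolerance = 1e-9)

  for (alpha in c(0.05, 0.01, 0.001)) {
    lo <- sum(anova_screen(adj, alpha = alpha / 5)$sig_anova)
    hi <- sum(anova_screen(adj, alpha = alpha)$sig_anova)
    expect_lte(lo, hi)
  }
})
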