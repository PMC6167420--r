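fast_grid <- function() svm_grid(cost = 2^c(0, 5), gamma = 2^c(-7, -3),
                                 max_features = 50L)

## Two-class Gaussian fixture with optional planted mean separation in
## the first few features.
two_class_rows <- function(seed, n_per_class = 10L, p = 30L,
                           separation = 0, n_informative = 3L) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  y <- rep(c("AD", "NC"), each = n_per_class)
  X[y == "AD", seq_len(n_informative)] <-
    X[y == "AD", seq_len(n_informative)] + separation
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(X = X, y = y)
}

test_that("min-max normalization follows the printed formula", {
  tr <- matrix(c(2, 4, 6), 3, 1)
  pp <- minmax_fit(tr)
  expect_equal(as.vector(minmax_apply(pp, tr)), c(0, 0.5, 1))
  ## no clipping of test rows outside the training range
  expect_equal(as.vector(minmax_apply(pp, matrix(8))), 1.5)
  ## constant training feature maps to 0 everywhere
  ppc <- minmax_fit(matrix(5, 3, 1))
  expect_equal(as.vector(minmax_apply(ppc, matrix(c(5, 9)))), c(0, 0))
  ## direct-formula oracle on a random split
  set.seed(60)
  Xtr <- matrix(rnorm(40), 8, 5); Xte <- matrix(rnorm(10), 2, 5)
  pp2 <- minmax_fit(Xtr)
  got <- minmax_apply(pp2, Xte)
  for (j in 1:5) {
    expect_equal(got[, j],
                 (Xte[, j] - min(Xtr[, j])) /
                   (max(Xtr[, j]) - min(Xtr[, j])))
  }
  expect_true(all(minmax_apply(pp2, Xtr) >= 0 &
                    minmax_apply(pp2, Xtr) <= 1))
})

test_that("Welch ranking matches the printed formula with its degenerate
           sentinels", {
  X <- cbind(a = c(1, 2, 3, 4, 5, 6))
  rk <- welch_rank(X, rep(c("c1", "c2"), each = 3), positive = "c1")
  expect_equal(unname(rk$T["a"]), welch_t_oracle(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(abs(unname(rk$T["a"])), 3 / sqrt(2 / 3), tolerance = 1e-12)
  ## independent route: base R t.test Welch statistic
  expect_equal(unname(rk$T["a"]),
               unname(t.test(c(1, 2, 3), c(4, 5, 6))$statistic))

  ## label swap flips every sign, preserves ranking
  set.seed(61)
  Xr <- matrix(rnorm(60), 10, 6)
  y <- rep(c("A", "B"), 5)
  r1 <- welch_rank(Xr, y, positive = "A")
  r2 <- welch_rank(Xr, y, positive = "B")
  expect_equal(r1$T, -r2$T)
  expect_identical(r1$order, r2$order)

  ## zero variance, nonzero difference: infinite sentinel ranked first
  Xd <- cbind(c(rep(0, 3), rep(4, 3)), rnorm(6))
  rd <- welch_rank(Xd, rep(c("A", "B"), each = 3), positive = "A")
  expect_identical(rd$T[[1]], -Inf)
  expect_identical(rd$order[1], 1L)
  ## zero variance, zero difference: T = 0
  Xz <- cbind(rep(1, 6), rnorm(6))
  rz <- welch_rank(Xz, rep(c("A", "B"), each = 3), positive = "A")
  expect_identical(rz$T[[1]], 0)
})

test_that("AUC equals exhaustive pair counting with midrank ties", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12, 13),
                       rep(c("NC", "AD"), each = 3), "AD")$auc, 1)
  expect_equal(roc_auc(rep(0, 8), rep(c("AD", "NC"), 4), "AD")$auc, 0.5)
  for (seed in 1:20) {
    set.seed(seed)
    sc <- sample(1:6, 12, replace = TRUE)  # many ties
    lab <- sample(rep(c("AD", "NC"), each = 6))
    got <- roc_auc(sc, lab, "AD")
    expect_equal(got$auc, auc_oracle(sc, lab, "AD"))
    ## independent route: pROC
    expect_equal(got$auc,
                 as.numeric(pROC::auc(pROC::roc(
                   lab, sc, levels = c("NC", "AD"),
                   direction = "<", quiet = TRUE))))
    expect_equal(max(got$curve$tpr), 1)
    expect_equal(max(got$curve$fpr), 1)
  }
  expect_error(roc_auc(1:3, rep("AD", 3)), "both classes")
})

test_that("nested LOOCV separates well-separated clusters perfectly", {
  d <- two_class_rows(70, n_per_class = 10L, p = 20L, separation = 6)
  cv <- nested_loocv(d$X, d$y, fast_grid(), k_features = 10L)
  expect_equal(unname(cv$summary["ACC"]), 1)
  expect_equal(unname(cv$summary["AUC"]), 1)
  expect_identical(cv$positive, "AD")
  ## decision values signed toward the positive class
  expect_true(all(cv$predictions$decision[d$y == "AD"] > 0))
})

test_that("a single strongly informative feature is selected in every
           outer fold", {
  d <- two_class_rows(71, n_per_class = 8L, p = 200L, separation = 0)
  set.seed(71)
  d$X[, 77] <- rnorm(16, 0, 0.1) + ifelse(d$y == "AD", 5, 0)
  cv <- nested_loocv(d$X, d$y, fast_grid(), k_features = 5L)
  expect_equal(unname(cv$selection_frequency[77]), 1)
})

test_that("feature-count selection respects the 200 cap and recovers a
           plateau", {
  d <- two_class_rows(72, n_per_class = 6L, p = 40L, separation = 4,
                      n_informative = 10L)
  expect_error(select_feature_count(d$X, d$y, counts = c(10, 300)),
               "\\[1, 200\\]")
  sel <- select_feature_count(d$X, d$y, fast_grid(),
                              counts = c(5L, 10L, 20L))
  expect_true(all(sel$curve$k <= 200))
  acc10 <- sel$curve$ACC[sel$curve$k == 10L]
  expect_gte(sel$best$summary[["ACC"]], acc10 - 0.02)
})

test_that("decision-value correlation with a score matches the direct
           formula", {
  d <- two_class_rows(73, n_per_class = 5L, p = 10L, separation = 6)
  cv <- nested_loocv(d$X, d$y, fast_grid(), k_features = 5L)
  ## affine-in-score construction: r = 1 (use decision as its own score)
  mm <- 2 * cv$predictions$decision + 3
  expect_equal(hyperplane_score_correlation(cv, mm)$r, 1)
  ## direct covariance-formula oracle on a toy subset
  s <- seq_len(6)
  x <- cv$predictions$decision[s]
  yv <- mm[s] + rnorm(6)
  got <- hyperplane_score_correlation(cv, c(yv, mm[-s]),
                                      subset = s)
  oracle <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(got$r, oracle, tolerance = 1e-12)
  expect_error(hyperplane_score_correlation(cv, mm, subset = 1:3),
               "fewer than 5")
})

test_that("repeated leave-4-out is seed-reproducible and solves
           separable data", {
  d <- two_class_rows(74, n_per_class = 8L, p = 15L, separation = 6)
  r1 <- repeated_leave_k_out(d$X, d$y, fast_grid(), k_features = 5L,
                             k = 4L, reps = 2L, seed = 9L)
  r2 <- repeated_leave_k_out(d$X, d$y, fast_grid(), k_features = 5L,
                             k = 4L, reps = 2L, seed = 9L)
  expect_identical(r1, r2)
  r3 <- repeated_leave_k_out(d$X, d$y, fast_grid(), k_features = 5L,
                             k = 4L, reps = 5L, seed = 10L)
  expect_equal(unname(r3$mean["ACC"]), 1)
  ## stratification: both classes appear in every held-out set of 4
  expect_true(all(!is.na(r3$replicates$SEN)))
  expect_true(all(!is.na(r3$replicates$SPE)))
})

test_that("outer folds that lose a class are an error", {
  set.seed(75)
  X <- matrix(rnorm(7 * 5), 7, 5)
  y <- c(rep("AD", 5), "NC", "NC")
  expect_error(nested_loocv(X, y, fast_grid(), 3L), "loses a class")
  expect_error(nested_loocv(X[1:5, ], y[1:5], fast_grid(), 3L),
               "at least 6|two classes")
})
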