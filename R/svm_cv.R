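## Nested leave-one-out RBF-SVM classification with Welch-t feature
## ranking and train-side min-max normalization.
##
## Leakage discipline: normalization parameters, ranking statistics and
## the (cost, gamma) pair used in any fold are computed from that fold's
## training rows alone. The permutation-null test in the suite is the
## behavioural check of this invariant.

#' Min-max normalization parameters
#'
#' Learns per-feature `Xmin`/`Xmax` from training rows only; applied via
#' `(x - Xmin) / (Xmax - Xmin)`. Training rows map into `[0, 1]`; test
#' rows may fall outside and are deliberately not clipped. A constant
#' training feature maps to 0 everywhere (zero denominator guarded; the
#' feature is inert).
#'
#' @param train numeric matrix of training rows.
#' @return list with `min`, `range` per feature.
#' @export
minmax_fit <- function(train) {
  stopifnot(is.matrix(train), nrow(train) >= 2)
  mn <- apply(train, 2, min)
  rg <- apply(train, 2, max) - mn
  list(min = mn, range = rg)
}

#' @rdname minmax_fit
#' @param params parameters from `minmax_fit`.
#' @param rows matrix of rows to normalize.
#' @export
minmax_apply <- function(params, rows) {
  rg <- ifelse(params$range > 0, params$range, 1)
  out <- sweep(sweep(rows, 2, params$min), 2, rg, `/`)
  out[, params$range == 0] <- 0
  out
}

#' Welch t statistics for two-class feature ranking
#'
#' `T = (mu_c1 - mu_c2) / sqrt(s2_c1/n_c1 + s2_c2/n_c2)` per feature,
#' with sample variances (denominator n - 1). Degenerate features: zero
#' scale with zero mean difference gives T = 0; zero scale with a
#' nonzero difference gives a signed infinite sentinel (ranked first).
#'
#' @param rows numeric matrix (subjects x features).
#' @param labels two-class label vector.
#' @param positive which class plays c1 (default: first level).
#' @return Object of class `welch_rank`: list with `T` (statistics),
#'   `order` (feature indices by descending `|T|`, ties by index) and the
#'   per-class `mean`, `var`, `n`.
#' @export
welch_rank <- function(rows, labels, positive = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("exactly two classes required")
  if (is.null(positive)) positive <- levels(f)[1]
  i1 <- f == positive
  if (sum(i1) < 2 || sum(!i1) < 2) stop("both classes need >= 2 rows")
  X1 <- rows[i1, , drop = FALSE]; X2 <- rows[!i1, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- apply(X1, 2, stats::var); v2 <- apply(X2, 2, stats::var)
  se2 <- v1 / nrow(X1) + v2 / nrow(X2)
  T <- (m1 - m2) / sqrt(se2)
  zero <- se2 == 0
  T[zero] <- ifelse(m1[zero] == m2[zero], 0,
                    Inf * sign(m1[zero] - m2[zero]))
  ord <- order(-abs(T), seq_along(T))
  structure(list(T = T, order = ord,
                 mean = rbind(c1 = m1, c2 = m2),
                 var = rbind(c1 = v1, c2 = v2),
                 n = c(c1 = nrow(X1), c2 = nrow(X2)),
                 positive = positive),
            class = "welch_rank")
}

#' RBF-SVM hyperparameter grid
#'
#' Powers-of-two grid for the regularization constant and kernel width,
#' the canonical coarse grid of LIBSVM practice.
#'
#' @param cost candidate regularization values.
#' @param gamma candidate kernel-width values.
#' @param max_features cap on ranked features kept (<= 200; over-filtering
#'   guard).
#' @return list of class `svm_grid`.
#' @export
svm_grid <- function(cost = 2^seq(-5, 15, 2), gamma = 2^seq(-15, 3, 2),
                     max_features = 200L) {
  if (max_features > 200L) stop("max_features must be <= 200")
  structure(list(cost = sort(cost), gamma = sort(gamma),
                 max_features = as.integer(max_features)),
            class = "svm_grid")
}

## Train-side preparation for one fold: normalize on training rows,
## Welch-rank, keep top k features.
prepare_fold <- function(Xtr, ytr, k, positive) {
  params <- minmax_fit(Xtr)
  Xn <- minmax_apply(params, Xtr)
  rk <- welch_rank(Xn, ytr, positive)
  sel <- rk$order[seq_len(min(k, ncol(Xtr)))]
  list(params = params, selected = sel, X = Xn[, sel, drop = FALSE])
}

fit_rbf_svm <- function(X, y, cost, gamma) {
  e1071::svm(x = X, y = factor(y), type = "C-classification",
             kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE)
}

## Signed decision value with positive class > 0.
svm_decision <- function(model, newdata, positive) {
  pr <- stats::predict(model, newdata, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  cls <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]]
  d <- as.vector(dv)
  if (cls[2] == positive) d <- -d
  list(label = as.character(pr), decision = d)
}

## Grid search by LOOCV on (X, y): per inner fold re-normalize and
## re-rank on the inner training rows. Returns the winning (cost, gamma)
## (ties: smallest cost, then smallest gamma).
grid_search_loocv <- function(X, y, grid, k, positive) {
  combos <- expand.grid(gamma = grid$gamma, cost = grid$cost)
  combos <- combos[order(combos$cost, combos$gamma), ]
  n <- nrow(X)
  correct <- matrix(NA, n, nrow(combos))
  for (j in seq_len(n)) {
    ytr <- y[-j]
    if (length(unique(ytr)) < 2L ||
        min(table(ytr)) < 2L) next  # degenerate inner fold skipped
    prep <- prepare_fold(X[-j, , drop = FALSE], ytr, k, positive)
    xte <- minmax_apply(prep$params,
                        X[j, , drop = FALSE])[, prep$selected,
                                              drop = FALSE]
    for (ci in seq_len(nrow(combos))) {
      m <- fit_rbf_svm(prep$X, ytr, combos$cost[ci], combos$gamma[ci])
      correct[j, ci] <- as.character(stats::predict(m, xte)) ==
        as.character(y[j])
    }
  }
  acc <- colMeans(correct, na.rm = TRUE)
  best <- which.max(acc)  # first max: smallest cost then gamma
  list(cost = combos$cost[best], gamma = combos$gamma[best],
       inner_accuracy = acc[best])
}

classification_summary <- function(truth, pred, decision, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  pos <- truth == positive
  tp <- sum(pred == positive & pos); fn <- sum(pred != positive & pos)
  tn <- sum(pred != positive & !pos); fp <- sum(pred == positive & !pos)
  c(ACC = (tp + tn) / length(truth),
    SEN = tp / (tp + fn),
    SPE = tn / (tn + fp),
    AUC = roc_auc(decision, truth, positive)$auc)
}

#' Nested leave-one-out cross-validated RBF-SVM
#'
#' For each held-out subject: an inner LOOCV over the remaining training
#' rows — each inner fold re-normalizes (min-max) and re-ranks (Welch t)
#' on its own training rows, keeps the top `k_features`, and scores every
#' (cost, gamma) pair — selects the grid point with maximal inner
#' accuracy; the outer training set is then normalized and ranked afresh,
#' the chosen model fit, and the held-out subject predicted with its
#' decision value recorded.
#'
#' @param rows numeric matrix (subjects x features).
#' @param labels two-class labels.
#' @param grid an [svm_grid()].
#' @param k_features number of top-ranked features per fold
#'   (<= `grid$max_features`).
#' @param positive the positive (patient) class for SEN/SPE; default
#'   `"AD"` then `"aMCI"` if present, else the first factor level.
#' @return Object of class `cv_result`: list with `predictions`
#'   (data.frame: truth, predicted, decision value, fold cost/gamma),
#'   `summary` (ACC/SEN/SPE/AUC), `selection_frequency` (per feature,
#'   fraction of outer folds selecting it), `k_features`, `positive`.
#' @export
nested_loocv <- function(rows, labels, grid = svm_grid(),
                         k_features = 20L, positive = NULL) {
  stopifnot(is.matrix(rows))
  n <- nrow(rows)
  if (n < 6L) stop("need at least 6 subjects")
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L) stop("exactly two classes required")
  if (is.null(positive)) {
    positive <- intersect(c("AD", "aMCI"), labels)[1]
    if (is.na(positive)) positive <- sort(unique(labels))[1]
  }
  k_features <- min(k_features, grid$max_features, ncol(rows))
  pred <- character(n); dec <- numeric(n)
  cost_used <- numeric(n); gamma_used <- numeric(n)
  sel_count <- numeric(ncol(rows))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    ytr <- labels[tr]
    if (length(unique(ytr)) < 2L || min(table(ytr)) < 2L) {
      stop("outer fold ", i,
           " loses a class (or keeps < 2 rows of one) in training")
    }
    tuned <- grid_search_loocv(rows[tr, , drop = FALSE], ytr, grid,
                               k_features, positive)
    prep <- prepare_fold(rows[tr, , drop = FALSE], ytr, k_features,
                         positive)
    model <- fit_rbf_svm(prep$X, ytr, tuned$cost, tuned$gamma)
    xte <- minmax_apply(prep$params,
                        rows[i, , drop = FALSE])[, prep$selected,
                                                 drop = FALSE]
    out <- svm_decision(model, xte, positive)
    pred[i] <- out$label
    dec[i] <- out$decision
    cost_used[i] <- tuned$cost
    gamma_used[i] <- tuned$gamma
    sel_count[prep$selected] <- sel_count[prep$selected] + 1
  }
  predictions <- data.frame(
    subject = if (!is.null(rownames(rows))) rownames(rows)
              else seq_len(n),
    truth = labels, predicted = pred, decision = dec,
    cost = cost_used, gamma = gamma_used)
  structure(list(
    predictions = predictions,
    summary = classification_summary(labels, pred, dec, positive),
    selection_frequency = stats::setNames(sel_count / n,
                                          colnames(rows)),
    k_features = k_features, positive = positive),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<cv_result: n=%d, k=%d features, positive='%s'\n",
                     "  ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  AUC %.3f>\n"),
              nrow(x$predictions), x$k_features, x$positive,
              100 * s["ACC"], 100 * s["SEN"], 100 * s["SPE"], s["AUC"]))
  invisible(x)
}

#' Select the feature count maximizing outer accuracy
#'
#' Runs [nested_loocv()] for each candidate feature count and returns the
#' count with maximal outer accuracy (ties broken toward fewer features).
#' The count is tuned outside the outer loop, so the winning accuracy
#' carries an optimistic selection bias; treat the per-count curve, not
#' the maximum alone, as the estimate.
#'
#' @inheritParams nested_loocv
#' @param counts candidate feature counts (all <= 200).
#' @return list with `best_k`, `best` (its `cv_result`) and `curve`
#'   (data.frame of count vs ACC).
#' @export
select_feature_count <- function(rows, labels, grid = svm_grid(),
                                 counts = c(10L, 50L, 100L, 163L, 200L),
                                 positive = NULL) {
  counts <- sort(unique(as.integer(counts)))
  if (any(counts < 1L | counts > 200L)) stop("counts must lie in [1, 200]")
  results <- lapply(counts, function(k)
    nested_loocv(rows, labels, grid, k, positive))
  accs <- vapply(results, function(r) r$summary[["ACC"]], numeric(1))
  best <- which.max(accs)  # first max = smallest k on ties
  list(best_k = counts[best], best = results[[best]],
       curve = data.frame(k = counts, ACC = accs))
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' @param decision numeric scores (larger = more positive-class-like).
#' @param labels two-class labels.
#' @param positive positive class (default: first sorted label).
#' @return list with `auc` and `curve` (data.frame `fpr`, `tpr` over all
#'   score thresholds). Midranks handle ties, so identical scores for
#'   everyone give AUC 0.5.
#' @export
roc_auc <- function(decision, labels, positive = NULL) {
  labels <- as.character(labels)
  if (is.null(positive)) positive <- sort(unique(labels))[1]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(decision)  # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(decision), decreasing = TRUE))
  curve <- data.frame(
    fpr = vapply(thr, function(t) sum(decision >= t & !pos) / n0,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(decision >= t & pos) / n1,
                 numeric(1)))
  list(auc = auc, curve = curve)
}

#' Correlation between decision values and a cognitive score
#'
#' Pearson correlation of out-of-fold SVM decision values (the signed
#' distance-from-hyperplane surrogate) with a score such as MMSE, over a
#' subject subset.
#'
#' @param cv a `cv_result`.
#' @param score numeric vector aligned with the cv rows.
#' @param subset logical/index subset of rows (default all).
#' @return list with `r`, `p`, `n`.
#' @export
hyperplane_score_correlation <- function(cv, score, subset = NULL) {
  d <- cv$predictions$decision
  if (is.null(subset)) subset <- rep(TRUE, length(d))
  d <- d[subset]; s <- score[subset]
  if (length(d) < 5) stop("fewer than 5 subjects in subset")
  ct <- stats::cor.test(d, s, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(d))
}

#' Repeated stratified leave-k-out validation
#'
#' Each replicate holds out `k` subjects (class-stratified round-robin
#' where possible), tunes (cost, gamma) by LOOCV grid search on the
#' training rows with per-fold normalization and ranking — the same
#' train-side pipeline as an outer fold of [nested_loocv()] — fits the
#' winning model, and scores the held-out subjects.
#'
#' @inheritParams nested_loocv
#' @param k held-out subjects per replicate.
#' @param reps number of replicates.
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return list with `mean` and `sd` of per-replicate ACC/SEN/SPE, and
#'   `replicates` (per-replicate data.frame).
#' @export
repeated_leave_k_out <- function(rows, labels, grid = svm_grid(),
                                 k_features = 20L, k = 4L, reps = 1000L,
                                 seed = 1L, positive = NULL) {
  n <- nrow(rows)
  if (k >= n) stop("k must be smaller than the number of subjects")
  labels <- as.character(labels)
  if (is.null(positive)) {
    positive <- intersect(c("AD", "aMCI"), labels)[1]
    if (is.na(positive)) positive <- sort(unique(labels))[1]
  }
  k_features <- min(k_features, grid$max_features, ncol(rows))
  classes <- sort(unique(labels))
  set.seed(seed)
  out <- vector("list", reps)
  for (r in seq_len(reps)) {
    ## round-robin stratified draw of the k held-out subjects
    pools <- lapply(classes, function(cl) sample(which(labels == cl)))
    test <- integer(0)
    ci <- 1L
    while (length(test) < k) {
      cl <- ((ci - 1L) %% length(classes)) + 1L
      if (length(pools[[cl]])) {
        test <- c(test, pools[[cl]][1])
        pools[[cl]] <- pools[[cl]][-1]
      }
      ci <- ci + 1L
    }
    tr <- setdiff(seq_len(n), test)
    if (length(unique(labels[tr])) < 2L ||
        min(table(labels[tr])) < 2L) next  # degenerate fold skipped
    tuned <- grid_search_loocv(rows[tr, , drop = FALSE], labels[tr],
                               grid, k_features, positive)
    prep <- prepare_fold(rows[tr, , drop = FALSE], labels[tr],
                         k_features, positive)
    model <- fit_rbf_svm(prep$X, labels[tr], tuned$cost, tuned$gamma)
    xte <- minmax_apply(prep$params,
                        rows[test, , drop = FALSE])[, prep$selected,
                                                    drop = FALSE]
    pr <- as.character(stats::predict(model, xte))
    truth <- labels[test]
    pos <- truth == positive
    acc <- mean(pr == truth)
    sen <- if (any(pos)) mean(pr[pos] == positive) else NA_real_
    spe <- if (any(!pos)) mean(pr[!pos] != positive) else NA_real_
    out[[r]] <- data.frame(rep = r, ACC = acc, SEN = sen, SPE = spe)
  }
  skipped <- sum(vapply(out, is.null, logical(1)))
  if (skipped) message(skipped, " degenerate replicate(s) skipped")
  repsdf <- do.call(rbind, out)
  list(mean = colMeans(repsdf[, c("ACC", "SEN", "SPE")], na.rm = TRUE),
       sd = apply(repsdf[, c("ACC", "SEN", "SPE")], 2, stats::sd,
                  na.rm = TRUE),
       replicates = repsdf)
}
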