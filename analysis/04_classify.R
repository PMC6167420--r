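#!/usr/bin/env Rscript

## Step 4 — nested leave-one-out SVM classification.
##
## For each pairwise problem (AD-NC, aMCI-NC, AD-aMCI): min-max
## normalization and Welch-t feature ranking learned inside each training
## fold, RBF-SVM with (cost, gamma) tuned by an inner LOOCV grid search,
## outer LOOCV evaluation with ROC/AUC. The AD-NC decision values are
## correlated with MMSE, and a repeated stratified leave-4-out run checks
## stability. Small powers-of-two grid and 20 ranked features keep this
## driver at desk scale; widen via svm_grid() for a full run.

suppressPackageStartupMessages(library(hippradiomics))

tab <- read_feature_table("results/radiomics")
grid <- svm_grid(cost = 2^c(-1, 3, 7), gamma = 2^c(-9, -5),
                 max_features = 50L)
k_features <- 20L

dir.create("results", showWarnings = FALSE)
summaries <- list()
for (pair in list(c("AD", "NC"), c("aMCI", "NC"), c("AD", "aMCI"))) {
  keep <- tab$covariates$group %in% pair
  cv <- nested_loocv(tab$features[keep, ], tab$covariates$group[keep],
                     grid, k_features, positive = pair[1])
  tag <- paste0(tolower(pair[1]), "_", tolower(pair[2]))
  cat(sprintf("%s vs %s: ", pair[1], pair[2])); print(cv)
  write.csv(cv$predictions,
            sprintf("results/predictions_%s.csv", tag),
            row.names = FALSE)
  roc <- roc_auc(cv$predictions$decision, cv$predictions$truth,
                 cv$positive)
  write.csv(roc$curve, sprintf("results/roc_%s.csv", tag),
            row.names = FALSE)
  sel <- sort(cv$selection_frequency[cv$selection_frequency > 0],
              decreasing = TRUE)
  write.csv(data.frame(feature = names(sel), frequency = sel),
            sprintf("results/selection_frequency_%s.csv", tag),
            row.names = FALSE)
  summaries[[tag]] <- c(cv$summary, k = cv$k_features)

  if (identical(pair, c("AD", "NC"))) {
    hc <- hyperplane_score_correlation(cv, tab$covariates$mmse[keep])
    cat(sprintf("  decision value vs MMSE (AD+NC): r = %.2f, P = %.2g\n",
                hc$r, hc$p))
    l4 <- repeated_leave_k_out(tab$features[keep, ],
                               tab$covariates$group[keep], grid,
                               k_features, k = 4L, reps = 25L,
                               seed = 20260930L, positive = "AD")
    cat(sprintf("  leave-4-out x 25: ACC %.1f%% +/- %.1f%%\n",
                100 * l4$mean[["ACC"]], 100 * l4$sd[["ACC"]]))
  }
}

if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(summaries, "results/classification_summary.json",
                       auto_unbox = TRUE, digits = NA)
  cat("written: results/classification_summary.json\n")
}
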