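#!/usr/bin/env Rscript

## Step 3 — mass-univariate screening.
##
## Adjusts every feature for age and gender by linear regression, runs
## the three-group one-way ANOVA per feature with Bonferroni control at
## P < 0.01/1692, post hoc pairwise Welch tests, and Spearman
## correlations of features with MMSE over the pooled AD + aMCI subjects
## (P < 0.01) and with the four AVLT scores (P < 0.05). Writes the full
## per-feature result table and the heat-map-ready -log10(P) matrix.

suppressPackageStartupMessages(library(hippradiomics))

tab <- read_feature_table("results/radiomics")
adj <- adjust_covariates(tab)

scr <- posthoc_pairwise(anova_screen(adj), adj)
cat(sum(scr$sig_anova), "of", nrow(scr),
    "features differ across groups (Bonferroni P < 0.01/1692)\n")
multi <- summarize_multiregion(scr)
cat(multi$n_multi_region,
    "base features are altered in more than one subregion\n")
print(multi$per_subregion)

scr$rho_mmse <- spearman_screen(adj, "mmse")$rho
scr$p_mmse <- spearman_screen(adj, "mmse")$p_spearman
scr$sig_mmse <- scr$sig_anova & scr$p_mmse < 0.01
cat(sum(scr$sig_mmse),
    "group-different features also track MMSE in AD+aMCI (P < 0.01)\n")
for (sc in c("avlt_ir", "avlt_dr", "avlt_rp", "avlt_rn")) {
  sp <- spearman_screen(adj, sc, alpha = 0.05)
  scr[[paste0("rho_", sc)]] <- sp$rho
  scr[[paste0("sig_", sc)]] <- scr$sig_anova & sp$sig_spearman
}

dir.create("results", showWarnings = FALSE)
write.csv(scr, "results/screen_result.csv", row.names = FALSE)
write.csv(neglogp_matrix(scr), "results/neglogp_anova.csv")
cat("written: results/screen_result.csv, results/neglogp_anova.csv\n")
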