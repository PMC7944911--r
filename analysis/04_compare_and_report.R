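#!/usr/bin/env Rscript
# Statistical comparison: bootstrap the LOOCV classifier across K (matched
# resamples), ANOVA + Tukey HSD on the replicate AUC/accuracy/F1, and
# per-label Mann-Whitney U tests with Benjamini-Hochberg correction at the
# best K. Bootstrap runs at reduced settings (20 replicates over a K subset,
# 3 inner CV folds) to keep a desk-scale runtime; see the methods vignette.

library(gliosom)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

tables <- readRDS("results/feature_tables.rds")
cls <- readRDS("results/classification.rds")
best_k <- cls$best_k

cfg_boot <- svm_config(coarse_grid = 2^seq(-15, 15, by = 4), inner_folds = 3L,
                       seed = derive_seed(seed, "svm"))
compare_k <- intersect(c("4", "16"), names(tables))
boot <- bootstrap_performance(tables[compare_k], cfg_boot, n_boot = 20L,
                              seed = derive_seed(seed, "boot"))
print(boot)
for (m in c("auc", "accuracy", "f1")) {
  res <- anova_tukey(boot, m)
  cat(sprintf("%s: ANOVA F(%d, %d) = %.2f, p = %.4g\n", m,
              res$anova[["df1"]], res$anova[["df2"]],
              res$anova[["F"]], res$anova[["p"]]))
}

labels <- mannwhitney_bh(tables[[as.character(best_k)]], alpha = 0.05)
cat("per-label Mann-Whitney (BH-adjusted) at K =", best_k, ":\n")
print(labels, digits = 3)
write.csv(labels, "results/label_tests.csv", row.names = FALSE)
saveRDS(boot, "results/bootstrap.rds")

sig <- labels$label[labels$significant]
cat("labels with significant genotype differences:",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
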