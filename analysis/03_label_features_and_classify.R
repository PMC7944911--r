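#!/usr/bin/env Rscript
# Paint tumor voxels with their nearest protocluster's K-class label, build
# the log10(p + 1e-2) label-ratio feature tables, and run the LOOCV linear
# SVM (nested two-step grid search for C) for every K, with and without age
# at the best K. Writes results/loocv_metrics.csv and feature-table CSVs.

library(gliosom)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cohort <- read_cohort("results/cohort/manifest.csv")
clus <- readRDS("results/clustering.rds")

tables <- lapply(clus$partitions, function(part)
  build_feature_table(cohort$studies, clus$som, part, clus$params))
saveRDS(tables, "results/feature_tables.rds")
for (k in names(tables))
  write_feature_table(tables[[k]], sprintf("results/features_k%s.csv", k))

cfg <- svm_config(seed = derive_seed(seed, "svm"))
reports <- lapply(tables, loocv_classify, config = cfg)
metrics <- t(sapply(reports, function(r) r$metrics[1:7]))
metrics <- data.frame(K = as.integer(rownames(metrics)), metrics)
write.csv(metrics, "results/loocv_metrics.csv", row.names = FALSE)
cat("LOOCV metrics by K:\n")
print(metrics, digits = 3)

best_k <- metrics$K[which.max(metrics$auc)]
cat("best K by pooled LOOCV AUC:", best_k, "\n")

cfg_age <- svm_config(include_age = TRUE, seed = derive_seed(seed, "svm"))
rep_age <- loocv_classify(tables[[as.character(best_k)]], cfg_age)
cat("with age at K =", best_k, ":\n")
print(round(rep_age$metrics, 3))
saveRDS(list(reports = reports, report_age = rep_age, best_k = best_k),
        "results/classification.rds")
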