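#!/usr/bin/env Rscript
# Normalize each subject's channels (u = P75 + 1.5*IQR over brain voxels),
# sample the stride-4 voxel lattice, stack the cohort feature matrix, train
# the 20x20 batch SOM, and partition the 400 protoclusters with K-means for
# K in {4, 6, 8, 10, 12, 16, 20}. Saves the fitted objects under results/.

library(gliosom)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L

cohort <- read_cohort("results/cohort/manifest.csv")
params <- lapply(cohort$studies, compute_normalization)
blocks <- mapply(function(s, p) extract_training_voxels(s, p, stride = 4L),
                 cohort$studies, params, SIMPLIFY = FALSE)
features <- stack_cohort_features(blocks)
cat("stacked feature matrix: 6 x", ncol(features$values), "voxels\n")

som <- train_som(features, grid_shape = c(20L, 20L), epochs = 50L,
                 seed = derive_seed(seed, "som"))
cat("trained SOM:", nrow(som$weights), "protoclusters, quantization error",
    round(som$meta$quantization_error, 4), "\n")

partitions <- lapply(default_k_set(), function(K)
  cluster_protoclusters(som, K, restarts = 10L,
                        seed = derive_seed(seed, "kmeans", K)))
names(partitions) <- as.character(default_k_set())
cat("partitioned protoclusters for K =", paste(default_k_set(), collapse = ", "), "\n")

saveRDS(list(params = params, features = features, som = som,
             partitions = partitions),
        "results/clustering.rds")
cat("saved results/clustering.rds\n")
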