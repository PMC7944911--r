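# End-to-end orchestration: simulate -> preprocess -> cluster -> label
# features -> classify -> compare, with one top-level seed fanned out to
# per-stage streams and config-hash-stamped caching of stage outputs.

#' Pipeline configuration
#'
#' Defaults reproduce the study settings: stride-4 voxel sampling, a 20 x 20
#' SOM (400 protoclusters), K in {4, 6, 8, 10, 12, 16, 20}, 100 bootstrap
#' replicates, alpha = 0.05.
#'
#' @param cohort a [cohort_spec()] for the simulate stage.
#' @param channels channel subset used for clustering and labeling (default
#'   all six); dropping a channel runs the ablation variant of the analysis.
#' @param stride sampling stride in voxels.
#' @param grid_shape SOM grid `(rows, cols)`.
#' @param epochs SOM batch epochs.
#' @param k_values second-level class counts to evaluate.
#' @param kmeans_restarts k-means++ restarts per K.
#' @param svm an [svm_config()].
#' @param n_boot bootstrap replicates for the comparison stage.
#' @param compare_k subset of `k_values` carried into the bootstrap
#'   comparison (defaults to all of them).
#' @param alpha significance level.
#' @param seed top-level seed; every stage derives its own stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            channels = gliosom_channels(),
                            stride = 4L,
                            grid_shape = c(20L, 20L),
                            epochs = 50L,
                            k_values = default_k_set(),
                            kmeans_restarts = 10L,
                            svm = svm_config(),
                            n_boot = 100L,
                            compare_k = k_values,
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(all(compare_k %in% k_values))
  channels <- match.arg(channels, gliosom_channels(), several.ok = TRUE)
  structure(list(cohort = cohort, channels = channels, stride = as.integer(stride),
                 grid_shape = as.integer(grid_shape), epochs = as.integer(epochs),
                 k_values = as.integer(k_values),
                 kmeans_restarts = as.integer(kmeans_restarts),
                 svm = svm, n_boot = as.integer(n_boot),
                 compare_k = as.integer(compare_k),
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Load a cached stage result if its config hash matches, else compute and
# store it. Stage artifacts live under `outdir` as RDS with the hash stamped.
stage_cached <- function(outdir, name, hash, compute, use_cache = TRUE) {
  path <- file.path(outdir, paste0(name, ".rds"))
  if (use_cache && file.exists(path)) {
    obj <- readRDS(path)
    if (identical(obj$hash, hash)) {
      message("stage ", name, ": cache hit")
      return(list(value = obj$value, cached = TRUE))
    }
  }
  message("stage ", name, ": computing")
  value <- compute()
  saveRDS(list(hash = hash, value = value), path)
  list(value = value, cached = FALSE)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, cluster, features, classify and compare in
#' order, skipping stages whose cached outputs carry a matching config hash.
#' Changing any upstream setting (e.g. the stride) invalidates that stage and
#' everything downstream, because each stage's hash covers the configuration
#' of all stages feeding it.
#'
#' @param config a [pipeline_config()].
#' @param outdir run directory for artifacts (created if needed).
#' @param use_cache reuse hash-matching stage outputs?
#' @return List with the stage outputs (`cohort`, `features`, `som`,
#'   `partitions`, `tables`, `reports`, `comparison`), a `summary` naming the
#'   best K per metric, `stage_cached` flags, and the metrics JSON path.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("gliosom_run_"),
                         use_cache = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cached <- c()
  h_sim <- rlang::hash(config$cohort)

  sim <- stage_cached(outdir, "simulate", h_sim,
                      function() generate_cohort(config$cohort), use_cache)
  cohort <- sim$value
  cached["simulate"] <- sim$cached

  h_pre <- rlang::hash(list(h_sim, config$stride, config$channels))
  pre <- stage_cached(outdir, "preprocess", h_pre, function() {
    params <- lapply(cohort$subjects, function(s) compute_normalization(s$study))
    blocks <- lapply(seq_along(cohort$subjects), function(i)
      extract_training_voxels(cohort$subjects[[i]]$study, params[[i]],
                              stride = config$stride, channels = config$channels))
    list(params = params, features = stack_cohort_features(blocks))
  }, use_cache)
  cached["preprocess"] <- pre$cached

  h_clu <- rlang::hash(list(h_pre, config$grid_shape, config$epochs,
                            config$k_values, config$kmeans_restarts, config$seed))
  clu <- stage_cached(outdir, "cluster", h_clu, function() {
    som <- train_som(pre$value$features, grid_shape = config$grid_shape,
                     epochs = config$epochs,
                     seed = derive_seed(config$seed, "som"))
    partitions <- lapply(config$k_values, function(K)
      cluster_protoclusters(som, K, restarts = config$kmeans_restarts,
                            seed = derive_seed(config$seed, "kmeans", K),
                            allowed_k = config$k_values))
    names(partitions) <- as.character(config$k_values)
    list(som = som, partitions = partitions)
  }, use_cache)
  cached["cluster"] <- clu$cached

  h_feat <- rlang::hash(list(h_clu))
  feat <- stage_cached(outdir, "features", h_feat, function() {
    studies <- lapply(cohort$subjects, `[[`, "study")
    lapply(clu$value$partitions, function(part)
      build_feature_table(studies, clu$value$som, part,
                          params_list = pre$value$params))
  }, use_cache)
  cached["features"] <- feat$cached

  h_cls <- rlang::hash(list(h_feat, config$svm))
  cls <- stage_cached(outdir, "classify", h_cls, function() {
    cfg <- config$svm
    cfg$seed <- derive_seed(config$seed, "svm")
    lapply(feat$value, loocv_classify, config = cfg)
  }, use_cache)
  cached["classify"] <- cls$cached

  h_cmp <- rlang::hash(list(h_cls, config$n_boot, config$compare_k, config$alpha))
  cmp <- stage_cached(outdir, "compare", h_cmp, function() {
    cfg <- config$svm
    cfg$seed <- derive_seed(config$seed, "svm")
    boot <- bootstrap_performance(feat$value[as.character(config$compare_k)],
                                  cfg, n_boot = config$n_boot,
                                  seed = derive_seed(config$seed, "boot"))
    anova <- lapply(c(auc = "auc", accuracy = "accuracy", f1 = "f1"),
                    function(m) anova_tukey(boot, m))
    best_k <- as.integer(names(which.max(colMeans(boot$metrics$auc))))
    labels <- mannwhitney_bh(feat$value[[as.character(best_k)]],
                             alpha = config$alpha)
    list(bootstrap = boot, anova = anova, best_k = best_k, label_tests = labels)
  }, use_cache)
  cached["compare"] <- cmp$cached

  metric_tbl <- t(sapply(cls$value, function(r) unname(r$metrics[1:7])))
  colnames(metric_tbl) <- names(cls$value[[1]]$metrics)
  summary <- list(
    best_k_by_metric = lapply(
      stats::setNames(colnames(metric_tbl), colnames(metric_tbl)),
      function(m) as.integer(rownames(metric_tbl)[which.max(metric_tbl[, m])])),
    loocv_metrics = metric_tbl,
    bootstrap_best_k = cmp$value$best_k)

  metrics_json <- file.path(outdir, "metrics.json")
  jsonlite::write_json(
    list(config_hash = rlang::hash(config),
         loocv = apply(metric_tbl, 1, as.list, simplify = FALSE),
         bootstrap_mean_auc = as.list(colMeans(cmp$value$bootstrap$metrics$auc)),
         bootstrap_best_k = cmp$value$best_k,
         label_tests = cmp$value$label_tests),
    metrics_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(config = config, outdir = outdir,
       cohort = cohort, params = pre$value$params, features = pre$value$features,
       som = clu$value$som, partitions = clu$value$partitions,
       tables = feat$value, reports = cls$value, comparison = cmp$value,
       summary = summary, stage_cached = cached, metrics_json = metrics_json)
}
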