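# Statistical comparison machinery: bootstrap of the classifier across K,
# one-way ANOVA + Tukey HSD on the replicate metrics, and per-label
# Mann-Whitney U tests with Benjamini-Hochberg correction.

#' Bootstrap the LOOCV classifier across candidate K values
#'
#' Each replicate resamples subjects with replacement, stratified by genotype
#' (so both classes always persist), and the same resampled cohort is fed to
#' [loocv_classify()] for every K — the ANOVA downstream therefore compares K
#' on matched resamples. Duplicated subjects are treated as distinct
#' resampled units inside the LOOCV.
#'
#' @param tables named list of `label_ratio_table`s, one per K, all over the
#'   same subjects.
#' @param config an [svm_config()].
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed; replicate r draws from a counter-derived stream.
#' @return A `bootstrap_result`: `n_boot`, `K` (names), and `metrics`, a list
#'   of `n_boot x length(K)` matrices for `auc`, `accuracy` and `f1`.
#' @export
bootstrap_performance <- function(tables, config = svm_config(), n_boot = 100L,
                                  seed = 1L) {
  if (!length(tables)) stop("no feature tables supplied")
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) as.character(t$K), character(1))
  ids <- lapply(tables, `[[`, "subject_ids")
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("all feature tables must cover the same subjects in the same order")
  if (n_boot < 2L) stop("n_boot must be >= 2")
  y <- tables[[1]]$genotype
  by_class <- split(seq_along(y), y)

  mk <- function() matrix(NA_real_, n_boot, length(tables),
                          dimnames = list(NULL, names(tables)))
  metrics <- list(auc = mk(), accuracy = mk(), f1 = mk())
  for (r in seq_len(n_boot)) {
    idx <- with_rng(derive_seed(seed, "replicate", r), {
      sort(unlist(lapply(by_class, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)])))
    })
    for (k_i in seq_along(tables)) {
      tab_r <- subset_feature_table(tables[[k_i]], idx)
      cfg_r <- config
      cfg_r$seed <- derive_seed(seed, "svm", r)
      rep <- loocv_classify(tab_r, cfg_r)
      metrics$auc[r, k_i] <- rep$metrics[["auc"]]
      metrics$accuracy[r, k_i] <- rep$metrics[["accuracy"]]
      metrics$f1[r, k_i] <- rep$metrics[["f1"]]
    }
  }
  structure(list(n_boot = as.integer(n_boot), K = names(tables),
                 metrics = metrics, seed = as.integer(seed)),
            class = "bootstrap_result")
}

#' One-way ANOVA and Tukey HSD across K groups of bootstrap replicates
#'
#' @param result a `bootstrap_result` (or any n_boot x groups matrix via
#'   `metric_matrix`).
#' @param metric `"auc"`, `"accuracy"` or `"f1"`.
#' @param metric_matrix optional matrix overriding `result`.
#' @return List with `anova` (F, df1, df2, p), `tukey` data.frame (pair,
#'   diff, lwr, upr, p_adj), and `note` (set when all groups are constant and
#'   equal, in which case no difference is reported).
#' @export
anova_tukey <- function(result, metric = c("auc", "accuracy", "f1"),
                        metric_matrix = NULL) {
  m <- if (!is.null(metric_matrix)) metric_matrix else {
    stopifnot(inherits(result, "bootstrap_result"))
    result$metrics[[match.arg(metric)]]
  }
  if (ncol(m) < 2L || nrow(m) < 2L)
    stop("need >= 2 groups with >= 2 replicates each")
  df <- data.frame(value = as.vector(m),
                   group = factor(rep(colnames(m), each = nrow(m)),
                                  levels = colnames(m)))
  df <- df[is.finite(df$value), , drop = FALSE] # degenerate replicates (NaN metrics)
  v <- if (nrow(df) > 1) stats::var(df$value) else NA_real_
  if (!is.finite(v) || v == 0 || length(unique(df$group)) < 2) {
    return(list(anova = c(F = NA_real_, df1 = ncol(m) - 1,
                          df2 = nrow(df) - ncol(m), p = NA_real_),
                tukey = NULL,
                note = "no replicate variation across groups: no differences to report"))
  }
  fit <- stats::aov(value ~ group, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(anova = c(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                 p = s$`Pr(>F)`[1]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       note = NULL)
}

#' Per-label Mann-Whitney U tests with Benjamini-Hochberg correction
#'
#' For each label row, the wild-type and mutant log-ratio values are compared
#' by a two-sided Mann-Whitney U test (exact for small untied samples, normal
#' approximation with continuity/tie correction otherwise). The K raw
#' p-values are then adjusted by the Benjamini-Hochberg step-up procedure.
#'
#' @param table a `label_ratio_table`.
#' @param alpha significance level for the adjusted flags.
#' @return Data frame: label, U (statistic for the wild-type group), p,
#'   p_adj, significant (adjusted p < alpha), direction (`"wildtype"` /
#'   `"mutant"` for the group with the larger median, `"none"` on ties).
#' @export
mannwhitney_bh <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "label_ratio_table"))
  wt <- table$genotype == "wildtype"
  if (!any(wt) || all(wt)) stop("both genotypes must be present")
  res <- lapply(seq_len(table$K), function(k) {
    x <- table$log_ratios[k, wt]
    y <- table$log_ratios[k, !wt]
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    p <- ht$p.value
    if (!is.finite(p)) p <- 1 # constant-in-both-groups degenerate case
    md <- stats::median(x) - stats::median(y)
    data.frame(label = k, U = unname(ht$statistic), p = p,
               direction = if (md > 0) "wildtype" else if (md < 0) "mutant" else "none")
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[, c("label", "U", "p", "p_adj", "significant", "direction")]
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates x K in {%s}\n",
              x$n_boot, paste(x$K, collapse = ", ")))
  cat("mean AUC by K:\n")
  print(round(colMeans(x$metrics$auc), 3))
  invisible(x)
}
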