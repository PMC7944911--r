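# Linear SVM genotype classifier: nested two-step grid search for the cost
# parameter, leave-one-out cross-validation, and the seven summary metrics.

#' Classifier configuration
#'
#' @param coarse_grid candidate costs for grid-search step 1; default the
#'   log2-spaced grid `2^(-15), 2^(-13), ..., 2^15`.
#' @param fine_steps number of multiplicative steps in grid-search step 2.
#' @param fine_span step 2 spans `[C/fine_span, C*fine_span]` around the
#'   coarse winner `C`, log-spaced.
#' @param inner_folds folds of the inner stratified CV scoring each candidate.
#' @param positive_class genotype treated as positive (`"wildtype"` default;
#'   both orientations are computable).
#' @param include_age append age, standardized on the training fold only, as
#'   an extra feature?
#' @param channel_subset optional character subset of [gliosom_channels()]
#'   recorded for upstream ablation runs (bookkeeping only at this stage).
#' @param seed integer seed for fold assignment.
#' @return An `svm_config` list.
#' @export
svm_config <- function(coarse_grid = 2^seq(-15, 15, by = 2),
                       fine_steps = 9L, fine_span = 4,
                       inner_folds = 5L,
                       positive_class = c("wildtype", "mutant"),
                       include_age = FALSE,
                       channel_subset = NULL,
                       seed = 1L) {
  positive_class <- match.arg(positive_class)
  if (any(coarse_grid <= 0) || fine_span <= 1 || fine_steps < 1)
    stop("cost candidates must be positive and fine_span > 1")
  if (inner_folds < 2L) stop("inner_cv folds must be >= 2")
  structure(list(coarse_grid = sort(coarse_grid), fine_steps = as.integer(fine_steps),
                 fine_span = fine_span, inner_folds = as.integer(inner_folds),
                 positive_class = positive_class, include_age = include_age,
                 channel_subset = channel_subset, seed = as.integer(seed)),
            class = "svm_config")
}

# Stratified fold assignment (shuffled within class), as a length-n integer
# vector of fold ids. Must be called inside an active RNG context.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_linear_svm <- function(X, y, cost, positive_class) {
  lev <- c(setdiff(unique(y), positive_class), positive_class)
  e1071::svm(x = X, y = factor(y, levels = lev), kernel = "linear",
             cost = cost, scale = FALSE)
}

# Predicted classes and decision values oriented so that positive values
# favor the positive class.
svm_predict <- function(model, newX, positive_class) {
  pr <- stats::predict(model, newX, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  pair <- strsplit(colnames(dv), "/")[[1]]
  sgn <- if (pair[1] == positive_class) 1 else -1
  list(predicted = as.character(pr), decision = sgn * as.numeric(dv[, 1]))
}

# Inner-CV accuracy of a single cost value under fixed fold ids.
inner_cv_accuracy <- function(X, y, cost, folds, positive_class) {
  hits <- 0L; total <- 0L
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    m <- fit_linear_svm(X[tr, , drop = FALSE], y[tr], cost, positive_class)
    p <- svm_predict(m, X[!tr, , drop = FALSE], positive_class)
    hits <- hits + sum(p$predicted == y[!tr])
    total <- total + sum(!tr)
  }
  if (total == 0L) return(NA_real_)
  hits / total
}

#' Two-step grid search for the SVM cost parameter
#'
#' Step 1 scores the coarse log2 grid by inner stratified-CV accuracy; step 2
#' scores a finer log-spaced grid centered on the coarse winner. Ties break
#' toward the smaller cost.
#'
#' @param X n x p feature matrix.
#' @param y character class labels.
#' @param config an [svm_config()].
#' @param seed seed for the fold assignment (default from config).
#' @return List with `cost` (the fine winner), `coarse_cost`, and the
#'   accuracy tables of both steps.
#' @export
two_step_grid_search <- function(X, y, config, seed = config$seed) {
  if (length(unique(y)) < 2L)
    stop("grid search needs both classes in the training set")
  k <- min(config$inner_folds, max(table(y)))
  folds <- with_rng(seed, stratified_folds(y, k))
  score <- function(grid) vapply(grid, function(C)
    inner_cv_accuracy(X, y, C, folds, config$positive_class), numeric(1))
  pick <- function(grid, acc) grid[which(acc == max(acc, na.rm = TRUE))[1]]

  coarse_acc <- score(config$coarse_grid)
  c0 <- pick(config$coarse_grid, coarse_acc)
  fine_grid <- c0 * config$fine_span^seq(-1, 1, length.out = config$fine_steps)
  fine_acc <- score(fine_grid)
  list(cost = pick(fine_grid, fine_acc), coarse_cost = c0,
       coarse = data.frame(cost = config$coarse_grid, accuracy = coarse_acc),
       fine = data.frame(cost = fine_grid, accuracy = fine_acc))
}

# Assemble the design matrix for a feature table; age is appended after
# standardization with training-fold parameters only.
design_matrix <- function(table, include_age, train_idx = NULL) {
  X <- t(table$log_ratios)
  if (include_age) {
    ref <- if (is.null(train_idx)) table$age else table$age[train_idx]
    s <- stats::sd(ref)
    if (!is.finite(s) || s == 0) s <- 1
    X <- cbind(X, age = (table$age - mean(ref)) / s)
  }
  X
}

#' Leave-one-out cross-validated SVM classification
#'
#' For every held-out subject the cost parameter is re-tuned by
#' [two_step_grid_search()] on the remaining subjects (no leakage), a linear
#' SVM is fitted, and the held-out prediction and signed decision value are
#' recorded. Metrics are computed by pooling all held-out decisions.
#'
#' @param table a `label_ratio_table`.
#' @param config an [svm_config()].
#' @return A `cv_report`: `per_subject` data.frame (subject_id, truth,
#'   predicted, decision), `confusion` counts, `metrics` (AUC, accuracy,
#'   sensitivity, specificity, precision, recall, F1), `chosen_cost` per
#'   fold, `config`, `config_hash`.
#' @export
loocv_classify <- function(table, config = svm_config()) {
  stopifnot(inherits(table, "label_ratio_table"))
  y <- table$genotype
  n <- length(y)
  if (min(table(y)) < 2L)
    stop("leave-one-out CV needs at least 2 subjects per class")
  if (all(apply(table$log_ratios, 1, function(r) stats::sd(r) == 0)))
    warning("feature table is degenerate (all rows constant); metrics will be NaN")

  predicted <- character(n)
  decision <- numeric(n)
  chosen <- numeric(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    Xall <- design_matrix(table, config$include_age, train_idx = tr)
    gs <- two_step_grid_search(Xall[tr, , drop = FALSE], y[tr], config,
                               seed = derive_seed(config$seed, "fold", i))
    m <- fit_linear_svm(Xall[tr, , drop = FALSE], y[tr], gs$cost,
                        config$positive_class)
    p <- svm_predict(m, Xall[i, , drop = FALSE], config$positive_class)
    predicted[i] <- p$predicted
    decision[i] <- p$decision
    chosen[i] <- gs$cost
  }
  metrics <- compute_metrics(decision, predicted, y, config$positive_class)
  structure(
    list(per_subject = data.frame(subject_id = table$subject_ids, truth = y,
                                  predicted = predicted, decision = decision,
                                  stringsAsFactors = FALSE),
         confusion = attr(metrics, "confusion"),
         metrics = metrics, chosen_cost = chosen,
         config = config, config_hash = rlang::hash(config)),
    class = "cv_report")
}

#' Area under the ROC curve by pairwise concordance
#'
#' @param scores numeric decision values.
#' @param is_pos logical, TRUE for positive-class subjects.
#' @return Fraction of (positive, negative) pairs ranked concordantly, ties
#'   counting one half.
#' @export
auc_concordance <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  if (!length(sp) || !length(sn)) stop("both classes must be present")
  cmp <- outer(sp, sn, "-")
  mean((cmp > 0) + 0.5 * (cmp == 0))
}

#' The seven classification metrics from pooled decisions
#'
#' AUC uses the pairwise-concordance formula over the pooled decision values;
#' the remaining metrics come from the confusion counts with the stated
#' positive class. Undefined ratios (zero denominators) are returned as NaN.
#'
#' @param decisions numeric decision values (larger favors positive class).
#' @param predictions predicted class labels.
#' @param truth true class labels.
#' @param positive_class label treated as positive.
#' @return Named numeric vector (auc, accuracy, sensitivity, specificity,
#'   precision, recall, f1) with the confusion counts attached as the
#'   `"confusion"` attribute.
#' @export
compute_metrics <- function(decisions, predictions, truth, positive_class) {
  stopifnot(length(decisions) == length(truth),
            length(predictions) == length(truth))
  if (length(unique(truth)) < 2L) stop("both classes must be present in truth")
  pos <- truth == positive_class
  tp <- sum(predictions == positive_class & pos)
  fp <- sum(predictions == positive_class & !pos)
  fn <- sum(predictions != positive_class & pos)
  tn <- sum(predictions != positive_class & !pos)
  ratio <- function(a, b) if (b == 0) NaN else a / b
  sens <- ratio(tp, tp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (!is.finite(prec) || !is.finite(sens) || prec + sens == 0) NaN else
    2 * prec * sens / (prec + sens)
  m <- c(auc = auc_concordance(decisions, pos),
         accuracy = (tp + tn) / length(truth),
         sensitivity = sens,
         specificity = ratio(tn, tn + fp),
         precision = prec,
         recall = sens,
         f1 = f1)
  attr(m, "confusion") <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  m
}

#' Write a cross-validation report as JSON
#'
#' Serializes the per-subject decisions, confusion counts, metrics, chosen
#' costs and configuration of a [loocv_classify()] report.
#'
#' @param report a `cv_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  jsonlite::write_json(
    list(per_subject = report$per_subject,
         confusion = as.list(report$confusion),
         metrics = as.list(unclass(report$metrics)[1:7]),
         chosen_cost = report$chosen_cost,
         config = report$config[setdiff(names(report$config), "coarse_grid")],
         coarse_grid = report$config$coarse_grid,
         config_hash = report$config_hash),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> n = %d, positive = %s\n",
              nrow(x$per_subject), x$config$positive_class))
  print(round(x$metrics, 3))
  invisible(x)
}
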