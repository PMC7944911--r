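test_that("AUC by concordance matches brute-force all-pairs counting", {
  withr::with_seed(4, {
    for (rep in 1:5) {
      n <- sample(10:50, 1)
      truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- c(TRUE, FALSE)
      scores <- round(rnorm(n), 1) # rounding forces some ties
      got <- auc_concordance(scores, truth)
      conc <- 0; tot <- 0
      for (i in which(truth)) for (j in which(!truth)) {
        tot <- tot + 1
        conc <- conc + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
      }
      expect_equal(got, conc / tot)
    }
  })
  expect_equal(auc_concordance(c(0.9, 0.6, 0.4, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_concordance(c(0.9, 0.1, 0.4, 0.6), c(TRUE, TRUE, FALSE, FALSE)), 0.5)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(8, {
    scores <- rnorm(40)
    truth <- rep(c(TRUE, FALSE), 20)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auc_concordance(scores, truth), ref, tolerance = 1e-12)
  })
})

test_that("metrics follow the confusion-matrix arithmetic and flag undefined cases", {
  # TP=3 FP=1 FN=1 TN=5
  truth <- c(rep("wildtype", 4), rep("mutant", 6))
  pred <- c("wildtype", "wildtype", "wildtype", "mutant",
            "wildtype", rep("mutant", 5))
  dec <- c(3, 2, 1, -0.5, 0.5, -1, -2, -3, -4, -5)
  m <- compute_metrics(dec, pred, truth, "wildtype")
  expect_equal(unname(m[c("precision", "recall", "f1", "accuracy")]),
               c(0.75, 0.75, 0.75, 0.8))
  expect_equal(attr(m, "confusion"), c(tp = 3L, fp = 1L, tn = 5L, fn = 1L))
  expect_equal(sum(attr(m, "confusion")), length(truth))
  expect_equal(unname(m["recall"]), unname(m["sensitivity"]))
  # no positive predictions: precision undefined, reported NaN not 0
  m2 <- compute_metrics(dec, rep("mutant", 10), truth, "wildtype")
  expect_true(is.nan(m2[["precision"]]))
  expect_error(compute_metrics(dec, pred, rep("wildtype", 10), "wildtype"),
               "both classes")
  # metrics invariant to monotone transforms of the decision values
  m3 <- compute_metrics(exp(dec), pred, truth, "wildtype")
  expect_equal(m3[["auc"]], m[["auc"]])
})

test_that("two-step grid search refines around the coarse winner, ties to smaller C", {
  tab <- separable_table()
  X <- t(tab$log_ratios)
  cfg <- svm_config(inner_folds = 2, seed = 3)
  gs <- two_step_grid_search(X, tab$genotype, cfg)
  expect_gte(gs$cost, gs$coarse_cost / cfg$fine_span)
  expect_lte(gs$cost, gs$coarse_cost * cfg$fine_span)
  # separable data: the returned C attains inner-CV accuracy 1
  expect_equal(max(gs$fine$accuracy, na.rm = TRUE), 1)
  expect_equal(gs$fine$accuracy[gs$fine$cost == gs$cost][1], 1)
  # single-candidate coarse grid: refinement stays centered on it
  cfg1 <- svm_config(coarse_grid = 1, inner_folds = 2, seed = 3)
  gs1 <- two_step_grid_search(X, tab$genotype, cfg1)
  expect_equal(gs1$coarse_cost, 1)
  expect_gte(gs1$cost, 0.25); expect_lte(gs1$cost, 4)
  # ties break toward the smaller cost (constant features: all C tie)
  Xc <- matrix(1, nrow(X), 2)
  gsc <- two_step_grid_search(Xc, tab$genotype, cfg)
  expect_equal(gsc$coarse_cost, min(cfg$coarse_grid))
  expect_error(two_step_grid_search(X, rep("wildtype", nrow(X)), cfg),
               "both classes")
})

test_that("LOOCV separates separable classes and sums confusion to n", {
  tab <- separable_table(n_per_class = 5)
  rep <- loocv_classify(tab, svm_config(inner_folds = 3, seed = 2))
  expect_equal(rep$metrics[["accuracy"]], 1)
  expect_equal(rep$metrics[["auc"]], 1)
  expect_equal(sum(rep$confusion), 10)
  expect_equal(nrow(rep$per_subject), 10)
  expect_length(rep$chosen_cost, 10)
})

test_that("label-permuted cohorts lose the class signal", {
  # Pooled LOOCV decision values are pessimistically biased under the null at
  # small n (the held-out subject's class is underrepresented in its training
  # fold), so permuted-label AUC sits at or below chance - never near the
  # separable cohort's 1.0.
  tab <- separable_table(n_per_class = 8, seed = 5)
  withr::with_seed(31, {
    aucs <- replicate(8, {
      tab_p <- tab
      tab_p$genotype <- sample(tab$genotype)
      loocv_classify(tab_p, svm_config(inner_folds = 2, seed = 1))$metrics[["auc"]]
    })
  })
  expect_lt(mean(aucs), 0.65)
  expect_gt(mean(aucs), 0.05)
  expect_true(all(aucs < 0.95))
})

test_that("no information leaks from the held-out subject", {
  # duplicating the held-out subject into training changes its decision value,
  # confirming the held-out subject did not influence its own fold
  tab <- separable_table(n_per_class = 4, seed = 9)
  withr::with_seed(1, tab$log_ratios <- tab$log_ratios +
    matrix(rnorm(length(tab$log_ratios), 0, 0.05), nrow(tab$log_ratios)))
  cfg <- svm_config(inner_folds = 2, seed = 7)
  base <- loocv_classify(tab, cfg)
  tab_dup <- gliosom:::subset_feature_table(tab, c(seq_along(tab$subject_ids), 1L))
  rep_dup <- loocv_classify(tab_dup, cfg)
  expect_false(isTRUE(all.equal(base$per_subject$decision[1],
                                rep_dup$per_subject$decision[1])))
})

test_that("age augmentation uses training-fold standardization and can drive separation", {
  withr::with_seed(13, {
    K <- 3; n <- 12
    ratios <- matrix(abs(rnorm(K * n)), K, n)
    ratios <- sweep(ratios, 2, colSums(ratios), "/") * 100
    genotype <- rep(c("wildtype", "mutant"), each = n / 2)
    age <- ifelse(genotype == "wildtype", rnorm(n, 70, 2), rnorm(n, 40, 2))
    tab <- make_table(ratios, genotype, age)
    cfg_no <- svm_config(inner_folds = 3, seed = 4)
    cfg_age <- svm_config(inner_folds = 3, seed = 4, include_age = TRUE)
    auc_no <- loocv_classify(tab, cfg_no)$metrics[["auc"]]
    auc_age <- loocv_classify(tab, cfg_age)$metrics[["auc"]]
    expect_gt(auc_age, auc_no)
    expect_equal(auc_age, 1)
  })
})

test_that("cv reports serialize to JSON with their metrics intact", {
  tab <- separable_table(n_per_class = 3)
  rep <- loocv_classify(tab, svm_config(inner_folds = 2, seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, f)
  got <- jsonlite::read_json(f)
  expect_equal(got$metrics$auc, rep$metrics[["auc"]])
  expect_equal(length(got$per_subject), 6)
  expect_equal(got$config_hash, rep$config_hash)
})

test_that("LOOCV requires two subjects per class and flags degenerate tables", {
  tab <- separable_table(n_per_class = 5)
  expect_error(loocv_classify(gliosom:::subset_feature_table(tab, c(1, 6)),
                              svm_config()), "2 subjects per class")
  const <- make_table(matrix(25, 4, 6), rep(c("wildtype", "mutant"), 3))
  expect_warning(loocv_classify(const, svm_config(inner_folds = 2)), "degenerate")
})
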