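make_labeled_fixture <- function(seed = 17, K = 4, n = 6) {
  coh <- generate_cohort(tiny_spec(n_subjects = n, seed = seed))
  params <- lapply(coh$subjects, function(s) compute_normalization(s$study))
  blocks <- mapply(function(s, p) extract_training_voxels(s$study, p),
                   coh$subjects, params, SIMPLIFY = FALSE)
  som <- train_som(stack_cohort_features(blocks), grid_shape = c(6L, 6L), epochs = 10)
  part <- cluster_protoclusters(som, K, seed = 1)
  list(coh = coh, params = params, som = som, part = part,
       studies = lapply(coh$subjects, `[[`, "study"))
}

test_that("label painting matches a brute-force BMU scan at full resolution", {
  fx <- make_labeled_fixture()
  st <- fx$studies[[1]]; params <- fx$params[[1]]
  map <- assign_labels(st, params, fx$som, fx$part)
  expect_equal(length(map$labels), sum(st$tumor_mask))
  expect_true(all(map$labels %in% seq_len(fx$part$K)))
  # exhaustive oracle over a sample of tumor voxels
  withr::with_seed(2, pick <- sample(nrow(map$coords), 25))
  for (v in pick) {
    xyz <- map$coords[v, ]
    vec <- vapply(gliosom_channels(), function(ch)
      st$channels[[ch]][xyz[1], xyz[2], xyz[3]] / unclass(params)[[ch]],
      numeric(1))
    d <- sqrt(colSums((t(fx$som$weights) - vec)^2))
    expect_equal(map$labels[v], fx$part$labels[which.min(d)])
  }
})

test_that("a tumor voxel equal to a node weight inherits that node's label", {
  fx <- make_labeled_fixture()
  st <- fx$studies[[2]]; params <- fx$params[[2]]
  node <- 13L
  xyz <- which(st$tumor_mask, arr.ind = TRUE)[1, ]
  for (c_i in seq_along(gliosom_channels())) {
    ch <- gliosom_channels()[c_i]
    st$channels[[ch]][xyz[1], xyz[2], xyz[3]] <-
      fx$som$weights[node, c_i] * unclass(params)[[ch]]
  }
  map <- assign_labels(st, params, fx$som, fx$part)
  v <- which(map$coords[, 1] == xyz[1] & map$coords[, 2] == xyz[2] &
               map$coords[, 3] == xyz[3])
  expect_equal(map$labels[v], fx$part$labels[node])
})

test_that("label ratios count voxels, sum to 100, and export round-trips", {
  fx <- make_labeled_fixture()
  map <- assign_labels(fx$studies[[3]], fx$params[[3]], fx$som, fx$part)
  p <- label_ratios(map)
  expect_equal(sum(p), 100, tolerance = 1e-9)
  expect_equal(p, 100 * tabulate(map$labels, map$K) / length(map$labels))
  # direct-count example: labels (1,1,2) with K = 2
  toy <- structure(list(labels = c(1L, 1L, 2L), K = 2L,
                        coords = cbind(1:3, 1L, 1L), dim = c(4L, 4L, 4L),
                        subject_id = "t", n_tumor_voxels = 3L),
                   class = "tumor_label_map")
  expect_equal(label_ratios(toy), c(200 / 3, 100 / 3))
  # volume export: 0 outside, labels inside, voxel count preserved
  vol <- label_map_volume(map)
  expect_equal(sum(vol > 0), map$n_tumor_voxels)
  expect_equal(sort(unique(as.vector(vol))), sort(unique(c(0L, map$labels))))
  # single-label map
  toy$labels <- c(2L, 2L, 2L)
  expect_equal(label_ratios(toy), c(0, 100))
})

test_that("log_ratio implements log10(p + 1e-2) on [0, 100] and is increasing", {
  expect_equal(log_ratio(0), -2)
  expect_equal(log_ratio(0.99), 0)
  expect_equal(log_ratio(100), log10(100.01))
  expect_equal(log_ratio(100), 2.0000434, tolerance = 1e-6)
  expect_error(log_ratio(-1), "percentages")
  expect_error(log_ratio(101), "percentages")
  p <- seq(0, 100, length.out = 50)
  expect_true(all(diff(log_ratio(p)) > 0))
})

test_that("the feature table matches per-subject recomputation and permutes with subjects", {
  fx <- make_labeled_fixture()
  tab <- build_feature_table(fx$studies, fx$som, fx$part, fx$params)
  expect_equal(dim(tab$log_ratios), c(4, 6))
  expect_equal(colSums(tab$ratios), rep(100, 6), ignore_attr = TRUE)
  # per-subject oracle
  for (i in c(1, 4)) {
    p_i <- label_ratios(assign_labels(fx$studies[[i]], fx$params[[i]],
                                      fx$som, fx$part))
    expect_equal(unname(tab$ratios[, i]), p_i)
    expect_equal(unname(tab$log_ratios[, i]), log_ratio(p_i))
  }
  # permuting subject order permutes columns identically
  perm <- c(3, 1, 6, 2, 5, 4)
  tab_p <- build_feature_table(fx$studies[perm], fx$som, fx$part, fx$params[perm])
  expect_equal(unname(tab_p$log_ratios), unname(tab$log_ratios[, perm]))
  expect_equal(tab_p$genotype, tab$genotype[perm])
  # a class absent from every tumor yields a -2 row
  absent <- which(rowSums(tab$ratios) == 0)
  if (length(absent))
    expect_true(all(tab$log_ratios[absent, ] == -2))
})

test_that("channel ablation runs the full labeling path on a channel subset", {
  coh <- generate_cohort(tiny_spec(n_subjects = 4, seed = 44))
  params <- lapply(coh$subjects, function(s) compute_normalization(s$study))
  keep <- setdiff(gliosom_channels(), "fdopa")
  blocks <- mapply(function(s, p)
    extract_training_voxels(s$study, p, channels = keep),
    coh$subjects, params, SIMPLIFY = FALSE)
  fm <- stack_cohort_features(blocks)
  expect_equal(nrow(fm$values), 5)
  som <- train_som(fm, grid_shape = c(4L, 4L), epochs = 5)
  expect_equal(colnames(som$weights), keep)
  part <- cluster_protoclusters(som, 4, seed = 1)
  tab <- build_feature_table(lapply(coh$subjects, `[[`, "study"),
                             som, part, params)
  expect_equal(dim(tab$log_ratios), c(4, 4))
  expect_equal(colSums(tab$ratios), rep(100, 4), ignore_attr = TRUE)
  cp <- component_planes(som, part)
  expect_equal(dim(cp$planes), c(4, 4, 5))
})

test_that("feature-table CSV export has the documented layout", {
  fx <- make_labeled_fixture(n = 4)
  tab <- build_feature_table(fx$studies[1:4], fx$som, fx$part, fx$params[1:4])
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  got <- utils::read.csv(f)
  expect_equal(got$row, c(paste0("label_", 1:4), "genotype", "age"))
  expect_equal(ncol(got), 5)
})
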