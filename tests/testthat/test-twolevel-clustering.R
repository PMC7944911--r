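test_that("the default grid yields 400 protocluster weight vectors", {
  withr::with_seed(1, {
    X <- matrix(runif(6 * 1000), 6, 1000)
    som <- train_som(X, epochs = 2)
    expect_equal(nrow(som$weights), 400)
    expect_equal(som$grid_shape, c(20L, 20L))
  })
})

test_that("protocluster count equals rows * cols for arbitrary grids", {
  withr::with_seed(2, {
    X <- matrix(runif(6 * 200), 6, 200)
    for (gs in list(c(3L, 5L), c(7L, 2L), c(10L, 10L))) {
      som <- train_som(X, grid_shape = gs, epochs = 3)
      expect_equal(nrow(som$weights), prod(gs))
      expect_true(all(is.finite(som$weights)))
    }
  })
})

test_that("identical inputs are a fixed point: all weights converge to the input", {
  v <- c(0.2, 0.4, 0.6, 0.8, 1.0, 1.2)
  X <- matrix(v, 6, 50)
  som <- train_som(X, grid_shape = c(4L, 4L), epochs = 5)
  expect_equal(unname(som$weights), matrix(v, 16, 6, byrow = TRUE), tolerance = 1e-10)
  expect_equal(som$meta$quantization_error, 0, tolerance = 1e-10)
})

test_that("training does not increase the quantization error", {
  withr::with_seed(7, {
    X <- matrix(runif(6 * 2000), 6, 2000)
    trained <- train_som(X, grid_shape = c(6L, 6L), epochs = 20)
    init_only <- train_som(X, grid_shape = c(6L, 6L), epochs = 0)
    expect_lte(trained$meta$quantization_error, quantization_error(init_only, X))
  })
})

test_that("training is deterministic and rejects bad inputs", {
  withr::with_seed(3, X <- matrix(runif(6 * 300), 6, 300))
  s1 <- train_som(X, grid_shape = c(5L, 5L), epochs = 5)
  s2 <- train_som(X, grid_shape = c(5L, 5L), epochs = 5)
  expect_identical(s1$weights, s2$weights)
  Xb <- X; Xb[1, 1] <- NaN
  expect_error(train_som(Xb, grid_shape = c(5L, 5L)), "NA/NaN")
  expect_error(train_som(X[, 1:10], grid_shape = c(5L, 5L)), "smaller grid")
})

test_that("bmu_index matches an exhaustive distance scan and breaks ties low", {
  som <- tiny_som()
  withr::with_seed(11, {
    V <- matrix(runif(6 * 100), 6, 100)
    got <- bmu_index(som, V)
    # brute-force argmin oracle
    oracle <- apply(V, 2, function(v) {
      d <- apply(som$weights, 1, function(w) sqrt(sum((w - v)^2)))
      which.min(d)
    })
    expect_equal(got, unname(oracle))
  })
  # exact-match and tie-break cases
  expect_equal(bmu_index(som, som$weights[7, ]), 7)
  som$weights[3, ] <- som$weights[12, ]
  expect_equal(bmu_index(som, som$weights[12, ]), 3)
  expect_error(bmu_index(som, c(1, 2, 3)), "length 6")
})

test_that("quantization error equals its brute-force recomputation", {
  som <- tiny_som()
  withr::with_seed(5, X <- matrix(runif(6 * 40), 6, 40))
  direct <- mean(apply(X, 2, function(v)
    min(sqrt(colSums((t(som$weights) - v)^2)))))
  expect_equal(quantization_error(som, X), direct, tolerance = 1e-12)
  # single node: mean distance to that weight
  som1 <- som; som1$weights <- som$weights[1, , drop = FALSE]
  expect_equal(quantization_error(som1, X),
               mean(sqrt(colSums((X - som$weights[1, ])^2))), tolerance = 1e-12)
  expect_error(quantization_error(som, X[, 0]), "empty")
})

test_that("k-means separates well-separated clouds and respects the allowed K set", {
  withr::with_seed(9, {
    som <- tiny_som(grid = c(4L, 4L))
    som$weights <- rbind(matrix(rnorm(8 * 6, 0, 0.01), 8, 6),
                         matrix(rnorm(8 * 6, 5, 0.01), 8, 6))
    part <- cluster_protoclusters(som, 2, seed = 1, allowed_k = NULL)
    expect_equal(part$labels[1:8], rep(part$labels[1], 8))
    expect_equal(part$labels[9:16], rep(part$labels[9], 8))
    expect_false(part$labels[1] == part$labels[9])
  })
  som <- tiny_som()
  expect_silent(p16 <- cluster_protoclusters(som, 16, seed = 1))
  expect_error(cluster_protoclusters(som, 5, seed = 1), "not in the configured set")
  expect_error(cluster_protoclusters(som, 17, seed = 1, allowed_k = NULL),
               "exceeds")
})

test_that("small-instance k-means attains the exhaustive-partition optimum", {
  withr::with_seed(21, {
    som <- tiny_som(grid = c(4L, 2L))
    W <- matrix(rnorm(8 * 6), 8, 6)
    som$weights <- W
    part <- cluster_protoclusters(som, 2, restarts = 10, seed = 4, allowed_k = NULL)
    # exhaustive search over all 2^8 assignments
    wss <- function(assign) {
      sum(vapply(unique(assign), function(g) {
        M <- W[assign == g, , drop = FALSE]
        sum(sweep(M, 2, colMeans(M))^2)
      }, numeric(1)))
    }
    best <- Inf
    for (code in 1:(2^8 - 2)) {
      assign <- as.integer(intToBits(code))[1:8]
      if (length(unique(assign)) == 2) best <- min(best, wss(assign))
    }
    expect_equal(part$meta$tot_withinss, best, tolerance = 1e-8)
  })
})

test_that("partitions are deterministic under a fixed seed, with size-ordered labels", {
  som <- tiny_som()
  p1 <- cluster_protoclusters(som, 4, seed = 8)
  p2 <- cluster_protoclusters(som, 4, seed = 8)
  expect_identical(p1, p2)
  expect_true(all(p1$labels %in% 1:4))
  expect_equal(sort(unique(p1$labels)), 1:4)
  sizes <- tabulate(p1$labels, 4)
  expect_true(all(diff(sizes) <= 0))
})

test_that("component planes mirror the weights and borderlines follow labels", {
  som <- tiny_som(grid = c(4L, 4L))
  part <- cluster_protoclusters(som, 4, seed = 2)
  cp <- component_planes(som, part)
  expect_equal(dim(cp$planes), c(4, 4, 6))
  # plane entry (i, j, c) is weight component c of node (i-1)*cols + j
  for (i in 1:4) for (j in 1:4)
    expect_equal(unname(cp$planes[i, j, 2]), unname(som$weights[(i - 1) * 4 + j, 2]))
  # uniform labels produce empty borderline masks
  part0 <- part; part0$labels <- rep(1L, 16)
  cp0 <- component_planes(som, part0)
  expect_false(any(cp0$border_right) || any(cp0$border_down))
  bad <- part; bad$labels <- bad$labels[1:9]
  expect_error(component_planes(som, bad), "grid")
})

test_that("T2 and ADC component planes correlate on a shared-latent cohort", {
  coh <- generate_cohort(tiny_spec(n_subjects = 6, seed = 14, latent_sd = 0.4))
  blocks <- lapply(coh$subjects, function(s) extract_training_voxels(s$study))
  som <- train_som(stack_cohort_features(blocks), grid_shape = c(8L, 8L), epochs = 15)
  cp <- component_planes(som)
  r <- cor(as.vector(cp$planes[, , "t2"]), as.vector(cp$planes[, , "adc"]),
           method = "spearman")
  expect_gt(r, 0.5)
})
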