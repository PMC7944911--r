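# First level of the two-level clustering: a batch self-organizing map whose
# nodes ("protoclusters") quantize the 6-D normalized voxel feature space.

as_feature_matrix <- function(features) {
  if (inherits(features, "voxel_feature_matrix")) features <- features$values
  if (!is.matrix(features) || nrow(features) < 1L)
    stop("features must be a channels x N matrix or a voxel_feature_matrix")
  features
}

# BMU assignment for X (N x 6) against node weights W (nodes x 6).
# Works on the affine score 2*X.W' - |W|^2 (argmax over nodes equals argmin of
# squared Euclidean distance); ties break to the lowest node index. Returns
# the squared distance to the BMU alongside.
bmu_scan <- function(X, W) {
  s <- 2 * (X %*% t(W))
  s <- s - rep(rowSums(W^2), each = nrow(s))
  bmu <- max.col(s, ties.method = "first")
  d2 <- rowSums(X^2) - s[cbind(seq_along(bmu), bmu)]
  list(bmu = bmu, dist2 = pmax(0, d2))
}

# Squared node positions on a rectangular grid, row-major node order
# (node = (row - 1) * cols + col).
grid_positions <- function(grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
}

#' Train a batch self-organizing map on the cohort voxel features
#'
#' Each epoch assigns every input vector to its best-matching unit (BMU) and
#' then replaces every node weight by the Gaussian-neighborhood-weighted mean
#' of all inputs, with the neighborhood radius shrinking linearly across
#' epochs. Weights are initialized on the plane spanned by the first two
#' principal components of the input, so training is deterministic.
#'
#' @param features a `voxel_feature_matrix` or 6 x N matrix of normalized
#'   intensities.
#' @param grid_shape `(rows, cols)` of the rectangular node grid; the default
#'   20 x 20 yields 400 protoclusters.
#' @param epochs number of batch epochs; `0` returns the (deterministic)
#'   principal-component initialization untouched.
#' @param radius `c(initial, final)` Gaussian neighborhood radius in grid
#'   units; default half the grid diagonal down to 1.
#' @param seed stored in the metadata for provenance (the batch algorithm
#'   itself is deterministic).
#' @return A `som_model`: `grid_shape`, `weights` (nodes x 6, row-major node
#'   order), and `meta` (epochs, radius schedule, seed, final quantization
#'   error, training size).
#' @export
train_som <- function(features, grid_shape = c(20L, 20L), epochs = 50L,
                      radius = NULL, seed = 1L) {
  fm <- as_feature_matrix(features)
  channel_names <- rownames(fm)
  if (is.null(channel_names) && nrow(fm) == 6L) channel_names <- GLIOSOM_CHANNELS
  X <- t(fm)
  d <- ncol(X)
  if (anyNA(X) || any(!is.finite(X))) stop("features contain NA/NaN/Inf values")
  n_nodes <- prod(grid_shape)
  if (nrow(X) < n_nodes)
    stop("fewer input vectors (", nrow(X), ") than SOM nodes (", n_nodes,
         "); use a smaller grid")
  if (is.null(radius))
    radius <- c(sqrt(sum((grid_shape - 1)^2)) / 2, 1)

  # linear initialization along the first two principal components
  m <- colMeans(X)
  Xc <- sweep(X, 2, m)
  eg <- eigen(crossprod(Xc) / max(1, nrow(X) - 1), symmetric = TRUE)
  fix_sign <- function(v) v * ifelse(v[which.max(abs(v))] < 0, -1, 1)
  pos <- grid_positions(grid_shape)
  span <- function(k, n) if (n > 1) 2 * (pos[, k] - 1) / (n - 1) - 1 else rep(0, n_nodes)
  W <- matrix(m, n_nodes, d, byrow = TRUE)
  for (k in seq_len(min(2, d))) {
    lam <- max(eg$values[k], 0)
    if (lam > 0)
      W <- W + outer(span(k, grid_shape[k]) * 2 * sqrt(lam), fix_sign(eg$vectors[, k]))
  }

  D2g <- as.matrix(stats::dist(pos))^2
  for (t in seq_len(epochs)) {
    sigma <- radius[1] + (radius[2] - radius[1]) *
      (if (epochs > 1) (t - 1) / (epochs - 1) else 1)
    bmu <- bmu_scan(X, W)$bmu
    S <- matrix(0, n_nodes, d)
    sums <- rowsum(X, bmu)
    S[as.integer(rownames(sums)), ] <- sums
    nk <- tabulate(bmu, n_nodes)
    H <- exp(-D2g / (2 * sigma^2))
    W <- (H %*% S) / as.vector(H %*% nk)
  }
  colnames(W) <- channel_names
  model <- structure(
    list(grid_shape = as.integer(grid_shape), weights = W,
         topology = "rectangular",
         meta = list(epochs = epochs, radius = radius, seed = seed,
                     n_train = nrow(X), quantization_error = NA_real_)),
    class = "som_model")
  model$meta$quantization_error <- quantization_error(model, t(X))
  model
}

#' Best-matching unit of one or more feature vectors
#'
#' @param som a `som_model`.
#' @param x a length-6 vector or 6 x m matrix of normalized intensities.
#' @return Integer node index/indices (row-major grid order) of the nearest
#'   protocluster by Euclidean distance; ties break to the lowest index.
#' @export
bmu_index <- function(som, x) {
  stopifnot(inherits(som, "som_model"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != ncol(som$weights))
    stop("feature vectors must have length ", ncol(som$weights))
  if (any(!is.finite(x))) stop("feature vectors must be finite")
  bmu_scan(t(x), som$weights)$bmu
}

#' Mean quantization error of a SOM on a feature set
#'
#' @param som a `som_model`.
#' @param features `voxel_feature_matrix` or 6 x N matrix.
#' @return Mean Euclidean distance of each input vector to its BMU weight.
#' @export
quantization_error <- function(som, features) {
  X <- t(as_feature_matrix(features))
  if (!nrow(X)) stop("features are empty")
  mean(sqrt(bmu_scan(X, som$weights)$dist2))
}

#' Component planes and inter-class borderlines
#'
#' Plane `c` holds weight component `c` of every node arranged on the grid;
#' the borderline masks mark grid edges whose two endpoint nodes carry
#' different K-class labels.
#'
#' @param som a `som_model`.
#' @param partition optional `protocluster_partition` fitted on this SOM.
#' @return List with `planes` (rows x cols x 6 array, channel-named) and, if
#'   a partition is given, `border_right` (rows x cols-1) and `border_down`
#'   (rows-1 x cols) logical edge masks.
#' @export
component_planes <- function(som, partition = NULL) {
  rows <- som$grid_shape[1]; cols <- som$grid_shape[2]
  d <- ncol(som$weights)
  planes <- array(NA_real_, c(rows, cols, d),
                  dimnames = list(NULL, NULL, colnames(som$weights)))
  for (c_i in seq_len(d))
    planes[, , c_i] <- matrix(som$weights[, c_i], rows, cols, byrow = TRUE)
  out <- list(planes = planes)
  if (!is.null(partition)) {
    if (length(partition$labels) != rows * cols)
      stop("partition was fitted on a different grid")
    L <- matrix(partition$labels, rows, cols, byrow = TRUE)
    out$border_right <- L[, -cols, drop = FALSE] != L[, -1, drop = FALSE]
    out$border_down <- L[-rows, , drop = FALSE] != L[-1, , drop = FALSE]
  }
  out
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %d x %d grid (%d protoclusters), %d epochs, QE %.4f\n",
              x$grid_shape[1], x$grid_shape[2], nrow(x$weights),
              x$meta$epochs, x$meta$quantization_error))
  invisible(x)
}
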