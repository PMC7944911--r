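# Second level of the two-level clustering: K-means over the protocluster
# weight vectors, giving each of the SOM nodes one of K class labels.

# Allowed numbers of second-level classes under the default configuration.
DEFAULT_K_SET <- c(4L, 6L, 8L, 10L, 12L, 16L, 20L)

#' Default set of second-level class counts
#' @return Integer vector `c(4, 6, 8, 10, 12, 16, 20)`.
#' @export
default_k_set <- function() DEFAULT_K_SET

# k-means++ seeding: D^2-weighted sampling of initial centers.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1] <- sample.int(n, 1L)
  d2 <- colSums((t(X) - X[centers[1], ])^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[k] <- sample.int(n, 1L)
    } else {
      centers[k] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, colSums((t(X) - X[centers[k], ])^2))
    }
  }
  X[centers, , drop = FALSE]
}

#' Cluster the SOM protoclusters into K classes
#'
#' Runs Lloyd's K-means with k-means++ seeding over the protocluster weight
#' vectors, keeping the best of `restarts` runs by total within-cluster sum
#' of squares. A run that converges with an empty class is re-seeded. Class
#' ids are relabeled in decreasing order of class size (ties by first
#' occurrence), so the labeling is deterministic and comparable across runs.
#'
#' @param som a `som_model`.
#' @param K number of classes; under the default configuration it must come
#'   from [default_k_set()].
#' @param restarts number of k-means++ restarts.
#' @param seed integer seed for seeding draws.
#' @param allowed_k integer vector of permitted K values, or `NULL` to allow
#'   any `2 <= K <=` number of protoclusters.
#' @return A `protocluster_partition`: `K`, `labels` (one id in 1..K per
#'   protocluster, node order matching the SOM), `centroids` (K x 6), and
#'   `meta` (restarts, seed, total within-class sum of squares).
#' @export
cluster_protoclusters <- function(som, K, restarts = 10L, seed = 1L,
                                  allowed_k = default_k_set()) {
  stopifnot(inherits(som, "som_model"))
  K <- as.integer(K)
  if (!is.null(allowed_k) && !(K %in% allowed_k))
    stop("K = ", K, " is not in the configured set {",
         paste(allowed_k, collapse = ", "), "}; pass allowed_k = NULL to override")
  W <- som$weights
  if (K > nrow(W)) stop("K = ", K, " exceeds the number of protoclusters (", nrow(W), ")")
  if (K < 2L) stop("K must be at least 2")

  best <- NULL
  with_rng(seed, {
    for (r in seq_len(restarts)) {
      km <- NULL
      for (attempt in 1:25) {
        km <- tryCatch(
          suppressWarnings(stats::kmeans(W, centers = kmeanspp_init(W, K),
                                         iter.max = 100L, algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(km) && all(km$size > 0)) break
        km <- NULL
      }
      if (is.null(km))
        stop("k-means failed to produce ", K, " non-empty classes after re-seeding")
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })

  # deterministic relabeling: class 1 = largest
  ord <- order(-best$size, seq_len(K))
  relabel <- integer(K)
  relabel[ord] <- seq_len(K)
  structure(
    list(K = K,
         labels = relabel[best$cluster],
         centroids = best$centers[ord, , drop = FALSE],
         meta = list(restarts = restarts, seed = seed,
                     tot_withinss = best$tot.withinss)),
    class = "protocluster_partition")
}

#' @export
print.protocluster_partition <- function(x, ...) {
  cat(sprintf("<protocluster_partition> K = %d over %d protoclusters, WSS %.4f\n",
              x$K, length(x$labels), x$meta$tot_withinss))
  invisible(x)
}
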