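#' Per-subject intensity normalization bounds
#'
#' For each channel, the upper bound is `u = P75 + 1.5 * IQR` of the in-brain
#' voxel intensities (percentiles by linear interpolation between order
#' statistics). Dividing by `u` maps the range `[0, u]` onto `[0, 1]`;
#' outliers above `u` are retained (they map above 1), never clipped.
#'
#' @param study a `gliosom_study`.
#' @return Named numeric vector of upper bounds, class `gliosom_norm`.
#' @export
compute_normalization <- function(study) {
  validate_study(study)
  idx <- which(study$brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  u <- vapply(GLIOSOM_CHANNELS, function(ch) {
    v <- study$channels[[ch]][idx]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q[2] + 1.5 * (q[2] - q[1])
  }, numeric(1))
  bad <- names(u)[!is.finite(u) | u <= 0]
  if (length(bad))
    stop("normalization bound is not positive for channel(s): ",
         paste(bad, collapse = ", "))
  structure(u, class = "gliosom_norm")
}

#' Normalize one channel volume
#'
#' @param volume 3-D numeric array in native channel units.
#' @param params a [compute_normalization()] result for the same study.
#' @param channel_id one of [gliosom_channels()].
#' @return The volume divided by its upper bound; values above the bound map
#'   above 1 and are retained.
#' @export
normalize_channel <- function(volume, params, channel_id) {
  stopifnot(inherits(params, "gliosom_norm"))
  channel_id <- match.arg(channel_id, GLIOSOM_CHANNELS)
  volume / unclass(params)[[channel_id]]
}

#' Normalize all channels of a study
#'
#' @param study a `gliosom_study`.
#' @param params its normalization bounds; computed if missing.
#' @return The study with normalized channels.
#' @export
normalize_study <- function(study, params = compute_normalization(study)) {
  for (ch in GLIOSOM_CHANNELS)
    study$channels[[ch]] <- normalize_channel(study$channels[[ch]], params, ch)
  study
}

#' Extract the stride-sampled training voxels of one subject
#'
#' Samples voxels on a fixed lattice with the given stride along each axis
#' (anchored at the first voxel), keeps only lattice points inside the brain
#' mask, and returns their six normalized intensities. With the default
#' stride of 4 this is one voxel in every 4 x 4 x 4 = 64.
#'
#' @param study a `gliosom_study`.
#' @param params normalization bounds from [compute_normalization()].
#' @param stride lattice stride in voxels (default 4).
#' @param channels channel subset to extract (default all six); dropping a
#'   channel here (e.g. FDOPA) runs the whole downstream pipeline as a
#'   channel-ablation analysis.
#' @return List with `values` (channels x n matrix, rows in channel order),
#'   `coords` (n x 3 integer voxel coordinates) and `subject_id`.
#' @export
extract_training_voxels <- function(study, params = compute_normalization(study),
                                    stride = 4L, channels = gliosom_channels()) {
  validate_study(study)
  channels <- match.arg(channels, GLIOSOM_CHANNELS, several.ok = TRUE)
  shape <- dim(study$brain_mask)
  ix <- seq(1L, shape[1], by = stride)
  iy <- seq(1L, shape[2], by = stride)
  iz <- seq(1L, shape[3], by = stride)
  sub_mask <- study$brain_mask[ix, iy, iz, drop = FALSE]
  sel <- which(sub_mask, arr.ind = TRUE)
  if (!nrow(sel))
    stop("no stride-", stride, " lattice point falls inside the brain mask of ",
         study$subject_id)
  coords <- cbind(ix[sel[, 1]], iy[sel[, 2]], iz[sel[, 3]])
  lin <- coords[, 1] + (coords[, 2] - 1L) * shape[1] +
    (coords[, 3] - 1L) * shape[1] * shape[2]
  values <- vapply(channels, function(ch) {
    normalize_channel(study$channels[[ch]], params, ch)[lin]
  }, numeric(nrow(coords)))
  values <- t(matrix(values, ncol = length(channels),
                     dimnames = list(NULL, channels)))
  list(values = values, coords = coords, subject_id = study$subject_id)
}

#' Stack per-subject voxel blocks into one cohort feature matrix
#'
#' Column-concatenates the per-subject blocks in the given (manifest) order.
#'
#' @param blocks list of [extract_training_voxels()] results.
#' @return A `voxel_feature_matrix`: list with `values` (6 x N), `subject_index`
#'   (length-N integer), `subject_ids`, and `coords` (N x 3).
#' @export
stack_cohort_features <- function(blocks) {
  if (!length(blocks)) stop("no feature blocks to stack")
  d <- nrow(blocks[[1]]$values)
  for (b in blocks)
    if (nrow(b$values) != d)
      stop("block for ", b$subject_id, " does not have ", d, " channel rows")
  values <- do.call(cbind, lapply(blocks, `[[`, "values"))
  ns <- vapply(blocks, function(b) ncol(b$values), integer(1))
  structure(
    list(values = values,
         subject_index = rep(seq_along(blocks), ns),
         subject_ids = vapply(blocks, `[[`, character(1), "subject_id"),
         coords = do.call(rbind, lapply(blocks, `[[`, "coords"))),
    class = "voxel_feature_matrix")
}

#' @export
print.voxel_feature_matrix <- function(x, ...) {
  cat(sprintf("<voxel_feature_matrix> %d x %d voxels from %d subject(s)\n",
              nrow(x$values), ncol(x$values), length(x$subject_ids)))
  invisible(x)
}

#' Write a cohort feature matrix with a JSON sidecar
#'
#' Writes the stacked voxel features as CSV (one row per sampled voxel:
#' subject_id, x, y, z, then one column per channel) plus a JSON sidecar
#' recording the channel order, stride, and per-subject normalization bounds.
#'
#' @param features a `voxel_feature_matrix`.
#' @param path_prefix output path prefix; writes `<prefix>_values.csv` and
#'   `<prefix>_meta.json`.
#' @param stride the stride used at extraction (recorded in the sidecar).
#' @param params_list optional list of per-subject normalization bounds.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_voxel_features <- function(features, path_prefix, stride = 4L,
                                 params_list = NULL) {
  stopifnot(inherits(features, "voxel_feature_matrix"))
  df <- data.frame(subject_id = features$subject_ids[features$subject_index],
                   x = features$coords[, 1], y = features$coords[, 2],
                   z = features$coords[, 3])
  df <- cbind(df, as.data.frame(t(features$values)))
  values_path <- paste0(path_prefix, "_values.csv")
  meta_path <- paste0(path_prefix, "_meta.json")
  utils::write.csv(df, values_path, row.names = FALSE)
  meta <- list(channels = rownames(features$values), stride = stride,
               n_voxels = ncol(features$values),
               subjects = features$subject_ids)
  if (!is.null(params_list))
    meta$normalization_bounds <- lapply(params_list, function(p)
      as.list(unclass(p)))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(values = values_path, meta = meta_path))
}
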