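# Label painting inside the tumor ROI and the per-subject label-fraction
# log-ratio features fed to the classifier.

#' Paint every tumor voxel with its nearest protocluster's K-class label
#'
#' Works at full native resolution (no stride): every tumor-mask voxel's
#' 6-D normalized vector is matched to its best-matching SOM node, and that
#' node's K-class label is recorded.
#'
#' @param study a `gliosom_study` (native intensities).
#' @param params the study's own normalization bounds.
#' @param som fitted `som_model`.
#' @param partition `protocluster_partition` fitted on `som`.
#' @return A `tumor_label_map`: `subject_id`, `coords` (n x 3), `labels`
#'   (ids in 1..K), `K`, `dim` (grid shape), `n_tumor_voxels`.
#' @export
assign_labels <- function(study, params, som, partition) {
  validate_study(study)
  if (length(partition$labels) != nrow(som$weights))
    stop("partition does not match the SOM's protocluster count")
  coords <- mask_coords(study$tumor_mask)
  if (!nrow(coords)) stop("tumor mask of ", study$subject_id, " is empty")
  lin <- which(study$tumor_mask)
  channels <- colnames(som$weights) # honors any upstream channel ablation
  X <- t(vapply(channels, function(ch) {
    normalize_channel(study$channels[[ch]], params, ch)[lin]
  }, numeric(length(lin))))
  if (length(lin) == 1L) X <- matrix(X, ncol = 1L, dimnames = list(channels, NULL))
  bmu <- bmu_index(som, X)
  structure(
    list(subject_id = study$subject_id, coords = coords,
         labels = partition$labels[bmu], K = partition$K,
         dim = dim(study$tumor_mask), n_tumor_voxels = nrow(coords)),
    class = "tumor_label_map")
}

#' Render a tumor label map as a full-grid integer volume
#'
#' @param map a `tumor_label_map`.
#' @return Integer array: 0 outside the tumor mask, the class id 1..K inside.
#' @export
label_map_volume <- function(map) {
  vol <- array(0L, dim = map$dim)
  vol[map$coords] <- map$labels
  vol
}

#' Per-class label fractions of one tumor
#'
#' @param map a `tumor_label_map`.
#' @return Length-K numeric vector of percentages; sums to 100.
#' @export
label_ratios <- function(map) {
  stopifnot(inherits(map, "tumor_label_map"), length(map$labels) > 0)
  100 * tabulate(map$labels, nbins = map$K) / length(map$labels)
}

#' Log-ratio transform of a label percentage
#'
#' The classifier feature for a label fraction `p` (in percent) is
#' `log10(p + 10^-2)`, so an absent label maps to -2 and a 0.99% label to 0.
#'
#' @param p percentage(s) in `[0, 100]`.
#' @return `log10(p + 0.01)`.
#' @export
log_ratio <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 100))
    stop("label ratios must be percentages in [0, 100]")
  log10(p + 1e-2)
}

#' Build the K x n_subjects label-ratio feature table
#'
#' @param studies list of `gliosom_study` in manifest order.
#' @param som fitted `som_model`.
#' @param partition `protocluster_partition` (defines K).
#' @param params_list optional list of per-study normalization bounds; each
#'   study's own bounds are computed when omitted.
#' @return A `label_ratio_table`: `K`, `ratios` and `log_ratios` (K x n
#'   matrices, columns in subject order), `subject_ids`, `genotype`, `age`.
#' @export
build_feature_table <- function(studies, som, partition, params_list = NULL) {
  if (!length(studies)) stop("no studies supplied")
  if (is.null(params_list)) params_list <- lapply(studies, compute_normalization)
  if (length(params_list) != length(studies))
    stop("params_list must align with studies")
  ratios <- vapply(seq_along(studies), function(i) {
    map <- assign_labels(studies[[i]], params_list[[i]], som, partition)
    label_ratios(map)
  }, numeric(partition$K))
  ratios <- matrix(ratios, nrow = partition$K)
  ids <- vapply(studies, `[[`, character(1), "subject_id")
  colnames(ratios) <- ids
  rownames(ratios) <- paste0("label_", seq_len(partition$K))
  structure(
    list(K = partition$K, ratios = ratios, log_ratios = log_ratio(ratios),
         subject_ids = ids,
         genotype = vapply(studies, `[[`, character(1), "genotype"),
         age = vapply(studies, `[[`, numeric(1), "age")),
    class = "label_ratio_table")
}

# Column-subset a feature table (used by the bootstrap; duplicate columns are
# kept as distinct resampled subjects with disambiguated ids).
subset_feature_table <- function(table, idx) {
  ids <- table$subject_ids[idx]
  dup <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ids <- ifelse(dup > 1, paste0(ids, ".", dup), ids)
  out <- list(K = table$K,
              ratios = table$ratios[, idx, drop = FALSE],
              log_ratios = table$log_ratios[, idx, drop = FALSE],
              subject_ids = ids,
              genotype = table$genotype[idx],
              age = table$age[idx])
  colnames(out$ratios) <- ids
  colnames(out$log_ratios) <- ids
  structure(out, class = "label_ratio_table")
}

#' Write a feature table as CSV
#'
#' Rows `label_1..label_K` plus `genotype` and `age`; columns are subjects.
#'
#' @param table a `label_ratio_table`.
#' @param path output CSV path.
#' @param what `"log_ratios"` (default) or `"ratios"`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, what = c("log_ratios", "ratios")) {
  what <- match.arg(what)
  m <- table[[what]]
  df <- as.data.frame(rbind(m, genotype = table$genotype, age = table$age))
  utils::write.csv(cbind(row = rownames(df), df), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.label_ratio_table <- function(x, ...) {
  cat(sprintf("<label_ratio_table> K = %d x %d subjects (%d wildtype / %d mutant)\n",
              x$K, length(x$subject_ids), sum(x$genotype == "wildtype"),
              sum(x$genotype == "mutant")))
  invisible(x)
}
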