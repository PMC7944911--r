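# Reporting: the tabular quantities behind the standard figures (component
# planes, label overlays + pie fractions, per-label box plots, radar charts),
# plus an optional ggplot2 renderer.

#' Tabular report data for a completed pipeline run
#'
#' Returns the numbers the report figures draw, so they can be checked
#' independently of any graphics device: per-subject label pie fractions,
#' per-label log-ratio distributions by genotype (with medians), and the
#' radar-chart coordinates (each class centroid's six normalized channel
#' values) for the chosen K.
#'
#' @param run a [run_pipeline()] result.
#' @param k which K to report (default: the bootstrap-best K).
#' @return List of data.frames: `pie` (subject_id, label, fraction),
#'   `box` (label, genotype, value) with `box_medians`, and `radar`
#'   (label, channel, value).
#' @export
report_tables <- function(run, k = run$comparison$best_k) {
  kc <- as.character(k)
  table <- run$tables[[kc]]
  part <- run$partitions[[kc]]
  if (is.null(table)) stop("no feature table for K = ", k)
  n <- length(table$subject_ids)
  pie <- data.frame(
    subject_id = rep(table$subject_ids, each = table$K),
    label = rep(seq_len(table$K), n),
    fraction = as.vector(table$ratios) / 100)
  box <- data.frame(
    label = rep(seq_len(table$K), n),
    genotype = rep(table$genotype, each = table$K),
    value = as.vector(table$log_ratios))
  box_medians <- stats::aggregate(value ~ label + genotype, data = box,
                                  FUN = stats::median)
  radar <- data.frame(
    label = rep(seq_len(part$K), ncol(part$centroids)),
    channel = rep(colnames(part$centroids), each = part$K),
    value = as.vector(part$centroids))
  list(pie = pie, box = box, box_medians = box_medians, radar = radar)
}

#' Render report figures for a completed run
#'
#' Writes PNG figures under `outdir`: the six SOM component planes with
#' inter-class borderlines, per-subject label-fraction bars (the pie-chart
#' ratios), per-label box-whisker plots of log-ratios by genotype, and radar
#' charts of each class centroid. Requires ggplot2.
#'
#' @param run a [run_pipeline()] result.
#' @param outdir output directory (default: `figures/` inside the run dir).
#' @param k which K to render (default: the bootstrap-best K).
#' @return Character vector of the written file paths, invisibly.
#' @export
render_report <- function(run, outdir = file.path(run$outdir, "figures"),
                          k = run$comparison$best_k) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("render_report requires the ggplot2 package")
  g <- function(...) ggplot2::ggplot(...)
  aes <- ggplot2::aes
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tabs <- report_tables(run, k)
  cp <- component_planes(run$som, run$partitions[[as.character(k)]])
  paths <- character(0)
  save_fig <- function(name, plot, w = 7, h = 5) {
    f <- file.path(outdir, paste0(name, ".png"))
    ggplot2::ggsave(f, plot, width = w, height = h, dpi = 150)
    paths <<- c(paths, f)
  }

  rows <- dim(cp$planes)[1]; cols <- dim(cp$planes)[2]
  plane_df <- do.call(rbind, lapply(dimnames(cp$planes)[[3]], function(ch) {
    data.frame(row = rep(seq_len(rows), cols),
               col = rep(seq_len(cols), each = rows),
               value = as.vector(cp$planes[, , ch]), channel = ch)
  }))
  seg_r <- which(cp$border_right, arr.ind = TRUE)
  seg_d <- which(cp$border_down, arr.ind = TRUE)
  borders <- rbind(
    if (nrow(seg_r)) data.frame(x = seg_r[, 2] + 0.5, xend = seg_r[, 2] + 0.5,
                                y = seg_r[, 1] - 0.5, yend = seg_r[, 1] + 0.5),
    if (nrow(seg_d)) data.frame(x = seg_d[, 2] - 0.5, xend = seg_d[, 2] + 0.5,
                                y = seg_d[, 1] + 0.5, yend = seg_d[, 1] + 0.5))
  p <- g(plane_df, aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("blue", "cyan", "yellow", "red")) +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(title = sprintf("SOM component planes (K = %d borderlines)", k),
                  x = NULL, y = NULL)
  if (!is.null(borders) && nrow(borders))
    p <- p + ggplot2::geom_segment(
      data = borders,
      aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend),
      inherit.aes = FALSE, linewidth = 0.3)
  save_fig("component_planes", p, w = 9, h = 6)

  save_fig("label_fractions",
           g(tabs$pie, aes(factor(.data$label), .data$fraction)) +
             ggplot2::geom_col(aes(fill = factor(.data$label)), show.legend = FALSE) +
             ggplot2::facet_wrap(~subject_id) +
             ggplot2::labs(x = "label", y = "fraction of tumor voxels"),
           w = 10, h = 8)

  save_fig("label_logratio_boxplots",
           g(tabs$box, aes(factor(.data$label), .data$value, fill = .data$genotype)) +
             ggplot2::geom_boxplot(outlier.size = 0.5) +
             ggplot2::labs(x = "label", y = "log10(p + 0.01)"))

  save_fig("radar_centroids",
           g(tabs$radar, aes(.data$channel, .data$value, group = 1)) +
             ggplot2::geom_polygon(fill = NA, colour = "steelblue") +
             ggplot2::geom_point(size = 0.8) +
             ggplot2::coord_polar() +
             ggplot2::facet_wrap(~label) +
             ggplot2::labs(x = NULL, y = "centroid value"),
           w = 9, h = 8)

  invisible(paths)
}

#' @importFrom rlang .data
NULL
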