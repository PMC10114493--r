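#' Plot a baseline-normalized cluster time series
#'
#' Relative total cluster area (and optionally relative cluster count)
#' against time from treatment onset, with the baseline window shaded.
#'
#' @param object A `spq_cluster_ts`.
#' @param what `"area"`, `"count"`, or `"both"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.spq_cluster_ts <- function(object, what = c("both", "area", "count"),
                                    ...) {
  what <- match.arg(what)
  tb <- object$frames
  long <- tidyr::pivot_longer(
    tb[, c("time_min", "relative_total_area", "relative_n_clusters")],
    cols = -"time_min", names_to = "metric", values_to = "relative")
  long$metric <- ifelse(long$metric == "relative_total_area",
                        "total cluster area", "cluster count")
  if (what == "area") long <- long[long$metric == "total cluster area", ]
  if (what == "count") long <- long[long$metric == "cluster count", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min, y = .data$relative,
                                     colour = .data$metric)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "time from treatment onset (min)",
                  y = "relative value (baseline = 1)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay detected clusters on a projection
#'
#' Raster of the projection with cluster outlines (pixels of labelled
#' components) highlighted, for manual verification of a threshold choice.
#'
#' @param frame_result A `spq_frame_clusters` from [detect_clusters()].
#' @param proj The projection that was analysed.
#' @return A ggplot object.
#' @export
plot_cluster_overlay <- function(frame_result, proj) {
  stopifnot(inherits(frame_result, "spq_frame_clusters"),
            inherits(proj, "spq_projection"))
  px <- proj$pixels
  df <- tidyr::expand_grid(y = seq_len(nrow(px)), x = seq_len(ncol(px)))
  df$intensity <- as.vector(t(px))
  lab <- frame_result$labels
  member <- which(lab > 0, arr.ind = TRUE)
  mdf <- tibble::tibble(y = member[, 1], x = member[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    (if (nrow(mdf)) ggplot2::geom_point(data = mdf, colour = "red",
                                        size = 0.1, alpha = 0.4) else NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Bar plot of spine densities per class
#'
#' @param density_tbl Output of [spine_density()] (one or more rows, e.g.
#'   bound over neurons with a `group` column).
#' @return A ggplot object.
#' @export
plot_spine_density <- function(density_tbl) {
  long <- tidyr::pivot_longer(
    density_tbl,
    cols = c("density_stubby", "density_thin", "density_mushroom"),
    names_to = "class", values_to = "density", names_prefix = "density_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$density)) +
    ggplot2::geom_col(position = "dodge", fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "spines per um of dendrite") +
    ggplot2::theme_minimal()
}
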