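#' Gaussian smoothing parameters
#'
#' The agglomeration step of the brightness-cluster analysis: a normalized,
#' truncated Gaussian "brush" that merges separate but closely positioned
#' bright pixels before thresholding.
#'
#' @param brush_size_px Odd integer kernel extent in pixels.
#' @param sigma_px Gaussian sigma in pixels; 0 disables smoothing.
#' @return A `spq_smoothing` parameter list.
#' @export
smoothing_params <- function(brush_size_px = 9L, sigma_px = 2) {
  if (brush_size_px < 1 || brush_size_px %% 2 == 0) {
    stop("brush_size_px must be an odd integer >= 1")
  }
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  structure(list(brush_size_px = as.integer(brush_size_px),
                 sigma_px = sigma_px), class = "spq_smoothing")
}

#' Cluster-detection parameters
#'
#' @param threshold Minimum brightness on the unit scale in \[0, 1\]; pixels
#'   strictly above it are cluster members (ties at the threshold are
#'   excluded).
#' @param use_smoothed_for_id If `TRUE` (default) and smoothing is supplied,
#'   membership is decided on the smoothed image; intensities are always
#'   measured on the raw projection.
#' @param connectivity 4 or 8 (default) for component labeling.
#' @param min_cluster_px Components smaller than this are dropped
#'   (single-pixel noise floor; default 4).
#' @return A `spq_cluster_params` list.
#' @export
cluster_params <- function(threshold = 0.4, use_smoothed_for_id = TRUE,
                           connectivity = 8L, min_cluster_px = 4L) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  stopifnot(connectivity %in% c(4L, 8L), min_cluster_px >= 1)
  structure(list(threshold = threshold,
                 use_smoothed_for_id = isTRUE(use_smoothed_for_id),
                 connectivity = as.integer(connectivity),
                 min_cluster_px = as.integer(min_cluster_px)),
            class = "spq_cluster_params")
}

#' Gaussian-blur a unit-scaled projection
#'
#' Convolution with a normalized, truncated Gaussian kernel of extent
#' `brush_size_px` and width `sigma_px`. Output stays in \[0, 1\]; a
#' constant image is unchanged for any parameters. Boundary handling is
#' circular (kernel normalization is exact everywhere).
#'
#' @param proj A unit-scaled [projection()].
#' @param params A [smoothing_params()].
#' @return A unit-scaled [projection()].
#' @export
gaussian_smooth <- function(proj, params) {
  stopifnot(inherits(proj, "spq_projection"), inherits(params, "spq_smoothing"))
  if (!proj$unit_scaled) stop("gaussian_smooth expects a unit-scaled projection")
  if (params$sigma_px == 0) return(proj)
  # kernel extent cannot exceed the image; shrink to the largest odd fit
  brush <- min(params$brush_size_px,
               2 * ((min(dim(proj$pixels)) - 1) %/% 2) + 1)
  k <- gaussian_kernel(brush, params$sigma_px)
  sm <- EBImage::filter2(proj$pixels, k)
  sm <- pmin(pmax(sm, 0), 1)
  projection(sm, pixel_size_um = proj$pixel_size_um, unit_scaled = TRUE,
             bit_depth = proj$bit_depth)
}

gaussian_kernel <- function(brush_size_px, sigma_px) {
  h <- (brush_size_px - 1) / 2
  d <- seq(-h, h)
  g <- exp(-d^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Detect brightness clusters inside an ROI
#'
#' The core of the brightness-cluster analysis: pixels inside the mask whose
#' (optionally smoothed) intensity is strictly greater than the brightness
#' threshold form the membership set; connected components at the stated
#' connectivity are the clusters, after dropping components smaller than
#' `min_cluster_px`. Per-cluster mean intensity is always measured on the
#' raw projection, and the ROI intensity partition (mean in-cluster vs.
#' non-cluster intensity) is reported alongside.
#'
#' @param proj A unit-scaled [projection()].
#' @param mask An `spq_mask` of the same shape with non-empty foreground.
#' @param params A [cluster_params()].
#' @param smoothing Optional [smoothing_params()] used only for membership.
#' @param frame_index Frame number recorded in the result.
#' @return A `spq_frame_clusters` object: fields `frame_index`,
#'   `clusters` (tibble: id, pixel_count, area_um2, mean_intensity,
#'   centroid_x, centroid_y), `n_clusters`, `total_area_um2`,
#'   `mean_in_cluster_intensity`, `mean_non_cluster_intensity`.
#' @export
detect_clusters <- function(proj, mask, params = cluster_params(),
                            smoothing = NULL, frame_index = 1L) {
  stopifnot(inherits(proj, "spq_projection"), inherits(mask, "spq_mask"))
  if (!proj$unit_scaled) stop("detect_clusters expects a unit-scaled projection")
  if (!identical(dim(proj$pixels), dim(mask$pixels))) {
    stop("projection and mask shapes differ")
  }
  if (sum(mask$pixels) == 0) stop("empty mask")
  id_img <- proj
  if (!is.null(smoothing) && params$use_smoothed_for_id) {
    id_img <- gaussian_smooth(proj, smoothing)
  }
  member <- (id_img$pixels > params$threshold) & (mask$pixels == 1)
  lab <- label_components(member, params$connectivity)
  px_area <- proj$pixel_size_um^2
  raw <- proj$pixels
  in_mask <- mask$pixels == 1
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= params$min_cluster_px)
  } else keep <- integer(0)
  if (length(keep)) {
    rows <- lapply(seq_along(keep), function(j) {
      ij <- which(lab == keep[j], arr.ind = TRUE)
      tibble::tibble(
        id = j,
        pixel_count = nrow(ij),
        area_um2 = nrow(ij) * px_area,
        mean_intensity = mean(raw[lab == keep[j]]),
        centroid_x = mean(ij[, 2]),
        centroid_y = mean(ij[, 1]))
    })
    clusters <- dplyr::bind_rows(rows)
    in_cluster <- lab %in% keep & lab > 0
    dim(in_cluster) <- dim(lab)
  } else {
    clusters <- tibble::tibble(
      id = integer(0), pixel_count = integer(0), area_um2 = numeric(0),
      mean_intensity = numeric(0), centroid_x = numeric(0),
      centroid_y = numeric(0))
    in_cluster <- matrix(FALSE, nrow(lab), ncol(lab))
  }
  non_cluster <- in_mask & !in_cluster
  structure(
    list(frame_index = as.integer(frame_index),
         clusters = clusters,
         n_clusters = nrow(clusters),
         total_area_um2 = sum(clusters$area_um2),
         mean_in_cluster_intensity =
           if (any(in_cluster)) mean(raw[in_cluster]) else NA_real_,
         mean_non_cluster_intensity =
           if (any(non_cluster)) mean(raw[non_cluster]) else NA_real_,
         labels = lab),
    class = "spq_frame_clusters")
}

#' @export
print.spq_frame_clusters <- function(x, ...) {
  cat(sprintf("<spq_frame_clusters> frame %d: %d cluster(s), %.3f um^2 total\n",
              x$frame_index, x$n_clusters, x$total_area_um2))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.spq_frame_clusters <- function(x, ...) x$clusters

#' Baseline-normalized cluster time series
#'
#' Runs [detect_clusters()] on every frame of a time-lapse with one
#' threshold for the whole series, then normalizes total cluster area and
#' cluster count so that the mean over the `baseline_n_frames` frames
#' immediately preceding the treatment frame equals 1.
#'
#' @param frames List of unit-scaled [projection()]s in acquisition order
#'   (one per time point).
#' @param mask Shared `spq_mask`.
#' @param params A [cluster_params()]; one threshold per series.
#' @param smoothing Optional [smoothing_params()].
#' @param treatment_frame 1-based index of the first post-treatment frame.
#' @param baseline_n_frames Number of pre-treatment frames averaged into the
#'   baseline (default 3; some experiments use 4).
#' @param frame_time_min Minutes between frames (default 3).
#' @return A `spq_cluster_ts` object whose `frames` field is a tibble with
#'   per-frame raw and relative metrics; `time_min` is minutes relative to
#'   treatment onset (last baseline frame = 0). If a baseline mean is zero
#'   the corresponding relative series is NA and flagged in
#'   `undefined_relative`.
#' @export
analyze_timeseries <- function(frames, mask, params = cluster_params(),
                               smoothing = NULL, treatment_frame,
                               baseline_n_frames = 3L, frame_time_min = 3) {
  n <- length(frames)
  if (treatment_frame - 1 < baseline_n_frames) {
    stop("need at least ", baseline_n_frames,
         " frames before the treatment frame")
  }
  if (treatment_frame > n) stop("treatment_frame beyond the series")
  res <- lapply(seq_len(n), function(i) {
    detect_clusters(frames[[i]], mask, params, smoothing, frame_index = i)
  })
  tb <- tibble::tibble(
    frame = seq_len(n),
    time_min = (seq_len(n) - treatment_frame + 1) * frame_time_min,
    n_clusters = vapply(res, `[[`, numeric(1), "n_clusters"),
    total_area_um2 = vapply(res, `[[`, numeric(1), "total_area_um2"),
    mean_cluster_area_um2 = ifelse(n_clusters > 0,
                                   total_area_um2 / n_clusters, NA_real_),
    mean_in_cluster_intensity =
      vapply(res, `[[`, numeric(1), "mean_in_cluster_intensity"),
    mean_non_cluster_intensity =
      vapply(res, `[[`, numeric(1), "mean_non_cluster_intensity"))
  base_idx <- (treatment_frame - baseline_n_frames):(treatment_frame - 1)
  base_area <- mean(tb$total_area_um2[base_idx])
  base_n <- mean(tb$n_clusters[base_idx])
  undefined <- character(0)
  if (base_area > 0) {
    tb$relative_total_area <- tb$total_area_um2 / base_area
  } else {
    tb$relative_total_area <- NA_real_
    undefined <- c(undefined, "relative_total_area")
  }
  if (base_n > 0) {
    tb$relative_n_clusters <- tb$n_clusters / base_n
  } else {
    tb$relative_n_clusters <- NA_real_
    undefined <- c(undefined, "relative_n_clusters")
  }
  structure(
    list(frames = tb, frame_results = res,
         treatment_frame = as.integer(treatment_frame),
         baseline_n_frames = as.integer(baseline_n_frames),
         frame_time_min = frame_time_min,
         baseline_total_area_um2 = base_area,
         baseline_n_clusters = base_n,
         undefined_relative = undefined),
    class = "spq_cluster_ts")
}

#' @export
print.spq_cluster_ts <- function(x, ...) {
  cat(sprintf(paste0("<spq_cluster_ts> %d frames, treatment at frame %d, ",
                     "baseline %d frames (mean area %.3f um^2)\n"),
              nrow(x$frames), x$treatment_frame, x$baseline_n_frames,
              x$baseline_total_area_um2))
  invisible(x)
}

#' @export
tidy.spq_cluster_ts <- function(x, ...) x$frames

#' @export
#' @importFrom generics glance
glance.spq_cluster_ts <- function(x, ...) {
  post <- x$frames$frame >= x$treatment_frame
  tibble::tibble(
    n_frames = nrow(x$frames),
    treatment_frame = x$treatment_frame,
    baseline_total_area_um2 = x$baseline_total_area_um2,
    baseline_n_clusters = x$baseline_n_clusters,
    peak_relative_total_area = if (any(post))
      max(x$frames$relative_total_area[post]) else NA_real_)
}

#' Mean cluster size before treatment and its post-treatment peak
#'
#' Before is the mean over the baseline frames of per-frame mean cluster
#' size (total area / cluster count); after is the highest per-frame mean
#' size among post-treatment frames within the first `after_window_min`
#' minutes, i.e. the maximum change in cluster size.
#'
#' @param series A `spq_cluster_ts` from [analyze_timeseries()].
#' @param after_window_min Window after onset searched for the peak
#'   (default 10 min).
#' @return A tibble with `before_um2`, `after_um2` and their ratio.
#' @export
summarize_before_after <- function(series, after_window_min = 10) {
  stopifnot(inherits(series, "spq_cluster_ts"))
  tb <- series$frames
  base_idx <- (series$treatment_frame - series$baseline_n_frames):
    (series$treatment_frame - 1)
  sizes <- tb$mean_cluster_area_um2[base_idx]
  if (all(is.na(sizes))) stop("no clusters in any baseline frame")
  before <- mean(sizes, na.rm = TRUE)
  post <- tb$frame >= series$treatment_frame &
    tb$time_min <= after_window_min
  if (!any(post)) stop("series does not span the after window")
  after <- max(tb$mean_cluster_area_um2[post], na.rm = TRUE)
  tibble::tibble(before_um2 = before, after_um2 = after,
                 ratio = after / before)
}
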