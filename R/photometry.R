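#' Mean intensity inside a circular ROI
#'
#' A pixel belongs to the ROI iff its centre lies within `radius_px` of the
#' ROI centre — the same membership rule as the observation-path mask
#' growth, kept consistent across the package.
#'
#' @param proj A [projection()].
#' @param x,y ROI centre in pixel coordinates (x rightward, y downward).
#' @param radius_px Positive radius in pixels; the disk must fit inside the
#'   image.
#' @return Mean intensity over the disk.
#' @export
roi_mean <- function(proj, x, y, radius_px) {
  stopifnot(inherits(proj, "spq_projection"), radius_px > 0)
  px <- proj$pixels
  if (x - radius_px < 1 || x + radius_px > ncol(px) ||
      y - radius_px < 1 || y + radius_px > nrow(px)) {
    stop("ROI disk does not fit inside the image")
  }
  r <- ceiling(radius_px)
  ys <- (round(y) - r):(round(y) + r)
  xs <- (round(x) - r):(round(x) + r)
  dd <- outer(ys - y, xs - x, function(a, b) sqrt(a^2 + b^2))
  sel <- dd <= radius_px
  mean(px[ys, xs][sel])
}

#' Reference-normalized spine/dendrite intensity ratio
#'
#' For each spine, equal-radius circular ROIs are placed in the spine head
#' and the adjacent dendrite. Mean signal intensity in each ROI is
#' normalized to the mean reference-channel (e.g. mCherry cell fill)
#' intensity in the same ROI, and the spine/dendrite ratio of these
#' normalized values is formed. The neuron-level value is the median over
#' spines; at least 10 spines per neuron are expected and fewer raises a
#' warning flag.
#'
#' @param signal,reference Unit-compatible [projection()]s of the signal
#'   and reference channels (same shape).
#' @param rois Data frame of paired ROIs, one row per spine, with columns
#'   `spine_x`, `spine_y`, `dendrite_x`, `dendrite_y`, `radius_px`.
#' @return A list of class `spq_ratio_result`: `per_spine` tibble with the
#'   per-spine ratios, `neuron_value` (median ratio), `n_spines`, and
#'   `low_n` flag.
#' @export
spine_dendrite_ratio <- function(signal, reference, rois) {
  stopifnot(inherits(signal, "spq_projection"),
            inherits(reference, "spq_projection"))
  if (!identical(dim(signal$pixels), dim(reference$pixels))) {
    stop("signal and reference shapes differ")
  }
  rois <- tibble::as_tibble(rois)
  need <- c("spine_x", "spine_y", "dendrite_x", "dendrite_y", "radius_px")
  if (!all(need %in% names(rois))) {
    stop("rois must have columns ", paste(need, collapse = ", "))
  }
  ratios <- vapply(seq_len(nrow(rois)), function(i) {
    r <- rois$radius_px[i]
    s_sp <- roi_mean(signal, rois$spine_x[i], rois$spine_y[i], r)
    r_sp <- roi_mean(reference, rois$spine_x[i], rois$spine_y[i], r)
    s_dd <- roi_mean(signal, rois$dendrite_x[i], rois$dendrite_y[i], r)
    r_dd <- roi_mean(reference, rois$dendrite_x[i], rois$dendrite_y[i], r)
    if (r_sp <= 0 || r_dd <= 0) stop("zero reference mean in an ROI")
    if (s_dd <= 0) stop("zero signal mean in a dendrite ROI")
    (s_sp / r_sp) / (s_dd / r_dd)
  }, numeric(1))
  n <- length(ratios)
  structure(
    list(per_spine = tibble::tibble(spine = seq_len(n), ratio = ratios),
         neuron_value = stats::median(ratios),
         n_spines = n, low_n = n < 10),
    class = "spq_ratio_result")
}

#' @export
print.spq_ratio_result <- function(x, ...) {
  cat(sprintf("<spq_ratio_result> %d spine(s), median ratio %.3f%s\n",
              x$n_spines, x$neuron_value,
              if (x$low_n) " [fewer than 10 spines]" else ""))
  invisible(x)
}

#' @export
tidy.spq_ratio_result <- function(x, ...) x$per_spine

#' @export
glance.spq_ratio_result <- function(x, ...) {
  tibble::tibble(neuron_value = x$neuron_value, n_spines = x$n_spines,
                 low_n = x$low_n)
}

#' Knock-down relative intensity against neighbouring somas
#'
#' Soma intensity of a transfected neuron divided by the mean intensity of
#' neighbouring non-transfected somas, then normalized to the mean relative
#' intensity of the scramble-shRNA control group.
#'
#' @param transfected_soma_mean Soma mean intensity of the transfected
#'   neuron.
#' @param neighbor_soma_means Numeric vector (>= 1) of neighbouring
#'   non-transfected soma intensities.
#' @param scramble_group_relatives Numeric vector of relative intensities
#'   (transfected / neighbour mean) from the scramble control group.
#' @return Normalized relative intensity (scalar).
#' @export
knockdown_relative_intensity <- function(transfected_soma_mean,
                                         neighbor_soma_means,
                                         scramble_group_relatives) {
  if (length(neighbor_soma_means) < 1) stop("need at least one neighbour")
  if (length(scramble_group_relatives) < 1) stop("scramble group is empty")
  nb <- mean(neighbor_soma_means)
  if (nb <= 0) stop("zero neighbour soma mean")
  rel <- transfected_soma_mean / nb
  rel / mean(scramble_group_relatives)
}

#' Pearson colocalization over an ROI
#'
#' Standard Pearson correlation coefficient between two channels over the
#' ROI pixels, without thresholding or background subtraction. Ranges from
#' -1 (anti-colocalization) through 0 (no correlation) to 1 (strong
#' colocalization).
#'
#' @param ch1,ch2 [projection()]s of the two channels (same shape).
#' @param roi An `spq_mask`; at least two pixels and neither channel
#'   constant within the ROI.
#' @return PCC in \[-1, 1\].
#' @export
pearson_cc <- function(ch1, ch2, roi) {
  stopifnot(inherits(ch1, "spq_projection"), inherits(ch2, "spq_projection"),
            inherits(roi, "spq_mask"))
  if (!identical(dim(ch1$pixels), dim(ch2$pixels)) ||
      !identical(dim(ch1$pixels), dim(roi$pixels))) {
    stop("channel and ROI shapes differ")
  }
  sel <- roi$pixels == 1
  if (sum(sel) < 2) stop("ROI must contain at least 2 pixels")
  a <- ch1$pixels[sel]; b <- ch2$pixels[sel]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("PCC undefined: a channel is constant within the ROI")
  }
  stats::cor(a, b)
}
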