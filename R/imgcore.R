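#' Calibrated grayscale image stack
#'
#' Container for a 3-D grayscale stack (z or time as the first axis) together
#' with its spatial calibration. Arrays are indexed `(z, y, x)` with y
#' increasing downward (raster order) and x rightward, matching TIFF page
#' layout.
#'
#' @param voxels Numeric 3-D array `(z, y, x)` of finite, non-negative
#'   intensities. A matrix is promoted to a single-slice stack.
#' @param pixel_size_um Lateral calibration, micrometres per pixel in x/y.
#' @param z_step_um Axial step between slices in micrometres (for time-lapse
#'   stacks this is nominal; use `frame_time_min`).
#' @param frame_time_min Optional minutes between frames for time-lapse
#'   stacks.
#' @param channel_name Optional free-text channel label.
#' @param bit_depth Bit depth of the source data (8 or 16); used by
#'   [to_unit_intensity()] in `"bit-depth"` mode.
#'
#' @return An object of class `spq_stack`.
#' @seealso [load_stack()], [max_project()]
#' @export
image_stack <- function(voxels, pixel_size_um = 0.0526, z_step_um = 0.2,
                        frame_time_min = NULL, channel_name = NULL,
                        bit_depth = NULL) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  stopifnot(is.array(voxels), length(dim(voxels)) == 3L)
  if (dim(voxels)[1] == 0L) stop("stack has zero slices")
  if (!all(is.finite(voxels)) || any(voxels < 0)) {
    stop("stack intensities must be finite and >= 0")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (z_step_um <= 0) stop("z_step_um must be > 0")
  structure(
    list(voxels = voxels, pixel_size_um = pixel_size_um,
         z_step_um = z_step_um, frame_time_min = frame_time_min,
         channel_name = channel_name, bit_depth = bit_depth),
    class = "spq_stack")
}

#' @export
print.spq_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<spq_stack> %d slice(s) of %d x %d px, %.4f um/px, dz %.2f um\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' 2-D projection image
#'
#' @param pixels Numeric matrix (y, x).
#' @param pixel_size_um Micrometres per pixel.
#' @param unit_scaled Logical; `TRUE` once intensities are mapped to
#'   \[0, 1\] (see [to_unit_intensity()]). Brightness thresholds are always
#'   interpreted on the unit scale.
#' @param bit_depth Bit depth of the source data, if known.
#'
#' @return An object of class `spq_projection`.
#' @export
projection <- function(pixels, pixel_size_um = 0.0526, unit_scaled = FALSE,
                       bit_depth = NULL) {
  stopifnot(is.matrix(pixels))
  if (!all(is.finite(pixels))) stop("projection intensities must be finite")
  if (isTRUE(unit_scaled) && (min(pixels) < 0 || max(pixels) > 1)) {
    stop("unit_scaled projection must have intensities in [0, 1]")
  }
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um,
         unit_scaled = isTRUE(unit_scaled), bit_depth = bit_depth),
    class = "spq_projection")
}

#' @export
print.spq_projection <- function(x, ...) {
  cat(sprintf("<spq_projection> %d x %d px, %.4f um/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              if (x$unit_scaled) "unit-scaled" else "raw intensities"))
  invisible(x)
}

#' Read a grayscale TIFF as a calibrated stack
#'
#' Reads a single- or multi-page grayscale TIFF; page order is preserved as
#' the z (or time) axis. Intensities are kept at their stored integer values
#' as floating point; bit depth is inferred from the data maximum when not
#' recorded in the file (<= 255 is taken as 8-bit, otherwise 16-bit).
#'
#' @param path Path to a TIFF file.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
load_stack <- function(path, pixel_size_um = 0.0526, z_step_um = 0.2,
                       frame_time_min = NULL, channel_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages")
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1)))) {
    stop("multi-sample (RGB) TIFF pages are not supported")
  }
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1)))) {
    stop("TIFF pages differ in size")
  }
  vox <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  bit_depth <- if (max(vox) > 255) 16L else 8L
  image_stack(vox, pixel_size_um = pixel_size_um, z_step_um = z_step_um,
              frame_time_min = frame_time_min, channel_name = channel_name,
              bit_depth = bit_depth)
}

#' Write a stack or projection to TIFF
#'
#' Stacks are written page-per-slice at their recorded bit depth (default
#' 16); unit-scaled projections are written as 32-bit float.
#'
#' @param x An `spq_stack` or `spq_projection`.
#' @param path Output file path.
#' @param bit_depth Integer bits per sample for integer data.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bit_depth = NULL) {
  if (inherits(x, "spq_stack")) {
    bd <- bit_depth %||% x$bit_depth %||% 16L
    mx <- 2^bd - 1
    pages <- lapply(seq_len(dim(x$voxels)[1]),
                    function(i) x$voxels[i, , ] / mx)
    tiff::writeTIFF(pages, path, bits.per.sample = bd)
  } else if (inherits(x, "spq_projection")) {
    if (x$unit_scaled) {
      tiff::writeTIFF(x$pixels, path, bits.per.sample = 32L)
    } else {
      bd <- bit_depth %||% x$bit_depth %||% 16L
      tiff::writeTIFF(x$pixels / (2^bd - 1), path, bits.per.sample = bd)
    }
  } else stop("unsupported object")
  invisible(path)
}

#' Maximum-intensity projection
#'
#' Collapses the z axis of a stack: each output pixel is the maximum over z
#' of that pixel column. Calibration is copied from the stack.
#'
#' @param stack An [image_stack()].
#' @return A [projection()] (not yet unit-scaled unless the stack values
#'   already lie in \[0, 1\]).
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "spq_stack"))
  v <- stack$voxels
  px <- apply(v, c(2L, 3L), max)
  projection(px, pixel_size_um = stack$pixel_size_um,
             unit_scaled = FALSE, bit_depth = stack$bit_depth)
}

#' Map projection intensities to the unit scale
#'
#' Brightness thresholds (e.g. the example value 0.4) are defined on the
#' \[0, 1\] scale, so raw projections must be unit-scaled before cluster
#' detection. `"bit-depth"` divides by the dtype maximum (255 or 65535);
#' `"min-max"` maps the observed \[min, max\] to \[0, 1\], with a constant
#' image mapping to all zeros.
#'
#' @param proj A raw [projection()].
#' @param mode `"bit-depth"` or `"min-max"`.
#' @param bit_depth Override for the bit depth in `"bit-depth"` mode.
#' @return A unit-scaled [projection()].
#' @export
to_unit_intensity <- function(proj, mode = c("bit-depth", "min-max"),
                              bit_depth = NULL) {
  stopifnot(inherits(proj, "spq_projection"))
  if (proj$unit_scaled) stop("projection is already unit-scaled")
  mode <- match.arg(mode)
  px <- proj$pixels
  if (mode == "bit-depth") {
    bd <- bit_depth %||% proj$bit_depth
    if (is.null(bd)) bd <- if (max(px) > 255) 16L else 8L
    out <- px / (2^bd - 1)
  } else {
    rng <- range(px)
    out <- if (rng[1] == rng[2]) px * 0 else (px - rng[1]) / diff(rng)
  }
  out <- pmin(pmax(out, 0), 1)
  projection(out, pixel_size_um = proj$pixel_size_um, unit_scaled = TRUE,
             bit_depth = proj$bit_depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
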