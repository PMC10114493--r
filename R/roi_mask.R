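#' One-pixel-wide dendrite skeleton image
#'
#' Wraps a binary image whose foreground is a hand-drawn (or synthetic)
#' one-pixel-wide 8-connected curve along a dendrite, drawn white on black.
#' Strokes thicker than one pixel are tolerated with a warning and thinned
#' by morphological skeletonization before use.
#'
#' @param pixels Binary matrix (logical or 0/1 numeric), foreground =
#'   skeleton.
#' @param pixel_size_um Micrometres per pixel.
#' @return An object of class `spq_skeleton`.
#' @export
skeleton_image <- function(pixels, pixel_size_um = 0.0526) {
  px <- as_binary(pixels)
  if (!is_thin(px)) {
    warning("skeleton contains >1-px-thick strokes; thinning first")
    px <- thin_binary(px)
  }
  structure(list(pixels = px, pixel_size_um = pixel_size_um),
            class = "spq_skeleton")
}

as_binary <- function(pixels) {
  stopifnot(is.matrix(pixels))
  px <- matrix(as.numeric(pixels != 0), nrow(pixels), ncol(pixels))
  px
}

# a foreground pixel with a completely filled 3x3 neighbourhood marks a
# stroke thicker than one pixel
is_thin <- function(px) {
  if (sum(px) == 0) return(TRUE)
  p <- pad_zero(px)
  nb <- shift_sum_full(p)
  !any(p == 1 & nb == 8)
}

pad_zero <- function(px, n = 1L) {
  out <- matrix(0, nrow(px) + 2 * n, ncol(px) + 2 * n)
  out[(n + 1):(n + nrow(px)), (n + 1):(n + ncol(px))] <- px
  out
}

shift_sum_full <- function(p) {
  nr <- nrow(p); nc <- ncol(p)
  s <- matrix(0, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- pmin(pmax(seq_len(nr) + dy, 1), nr)
    xs <- pmin(pmax(seq_len(nc) + dx, 1), nc)
    sh <- matrix(0, nr, nc)
    yv <- seq_len(nr) + dy; xv <- seq_len(nc) + dx
    oky <- yv >= 1 & yv <= nr; okx <- xv >= 1 & xv <= nc
    sh[oky, okx] <- p[yv[oky], xv[okx]]
    s <- s + sh
  }
  s
}

# Zhang-Suen thinning; adequate for occasional 2-px strokes
thin_binary <- function(px) {
  p <- pad_zero(px)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nr <- nrow(p); nc <- ncol(p)
      i <- 2:(nr - 1); j <- 2:(nc - 1)
      P2 <- p[i - 1, j];     P3 <- p[i - 1, j + 1]; P4 <- p[i, j + 1]
      P5 <- p[i + 1, j + 1]; P6 <- p[i + 1, j];     P7 <- p[i + 1, j - 1]
      P8 <- p[i, j - 1];     P9 <- p[i - 1, j - 1]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- P2 * P4 * P6 == 0 & P4 * P6 * P8 == 0
      } else {
        cond <- P2 * P4 * P8 == 0 & P2 * P6 * P8 == 0
      }
      del <- p[i, j] == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        sub <- p[i, j]; sub[del] <- 0; p[i, j] <- sub
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(p) - 1), 2:(ncol(p) - 1)]
}

#' @export
print.spq_skeleton <- function(x, ...) {
  cat(sprintf("<spq_skeleton> %d x %d px, %d foreground px, %.4f um/px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Grow a skeleton into an observation-path mask
#'
#' Dilates the one-pixel skeleton curve by a Euclidean disk: a pixel is
#' included iff its centre lies within `radius_px` of some skeleton pixel
#' centre. For a straight line this yields a band `2 * radius_px + 1` pixels
#' wide, so the default 95-px radius produces the 191-px-wide observation
#' path corresponding to 5 um on each side at 0.0526 um/px. A
#' Chebyshev-square structuring element is available for cross-checking.
#'
#' @param skeleton A [skeleton_image()].
#' @param radius_px Non-negative integer growth radius in pixels.
#' @param shape `"disk"` (Euclidean, default) or `"square"` (Chebyshev).
#' @return An object of class `spq_mask` carrying the grown binary mask,
#'   the growth radius and the skeleton length in micrometres.
#' @export
grow_skeleton <- function(skeleton, radius_px = 95L,
                          shape = c("disk", "square")) {
  stopifnot(inherits(skeleton, "spq_skeleton"))
  shape <- match.arg(shape)
  if (radius_px < 0) stop("radius_px must be >= 0")
  sk <- skeleton$pixels
  if (sum(sk) == 0) stop("empty skeleton")
  if (radius_px == 0) {
    mask <- sk
  } else if (shape == "disk") {
    # distance of every pixel to the nearest skeleton pixel
    d <- EBImage::distmap(1 - sk, metric = "euclidean")
    mask <- matrix(as.numeric(d <= radius_px), nrow(sk), ncol(sk))
  } else {
    mask <- chebyshev_dilate(sk, radius_px)
  }
  structure(
    list(pixels = mask, grow_radius_px = as.integer(radius_px),
         skeleton_length_um = skeleton_length_um(skeleton),
         pixel_size_um = skeleton$pixel_size_um),
    class = "spq_mask")
}

chebyshev_dilate <- function(px, r) {
  # separable max-filter: rows then columns
  run <- function(m, r) {
    out <- m
    for (d in seq_len(r)) {
      nr <- nrow(m)
      up <- rbind(m[(d + 1):nr, , drop = FALSE],
                  matrix(0, min(d, nr), ncol(m)))[seq_len(nr), , drop = FALSE]
      dn <- rbind(matrix(0, min(d, nr), ncol(m)),
                  m[seq_len(nr - d), , drop = FALSE])[seq_len(nr), , drop = FALSE]
      out <- pmax(out, up, dn)
    }
    out
  }
  v <- run(px, r)
  t(run(t(v), r))
}

#' Construct a mask object from a binary image
#'
#' For masks drawn or loaded directly rather than grown from a skeleton.
#'
#' @param pixels Binary matrix, foreground = included in analysis.
#' @param pixel_size_um Micrometres per pixel.
#' @param skeleton_length_um Optional dendrite length carried with the mask.
#' @return An `spq_mask`.
#' @export
roi_mask <- function(pixels, pixel_size_um = 0.0526,
                     skeleton_length_um = NA_real_) {
  structure(
    list(pixels = as_binary(pixels), grow_radius_px = NA_integer_,
         skeleton_length_um = skeleton_length_um,
         pixel_size_um = pixel_size_um),
    class = "spq_mask")
}

#' @export
print.spq_mask <- function(x, ...) {
  cat(sprintf("<spq_mask> %d x %d px, %d foreground px (%.1f um skeleton)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              x$skeleton_length_um))
  invisible(x)
}

#' Dendrite length from a skeleton curve
#'
#' Sums consecutive 8-connected steps along the skeleton: 1 px for
#' orthogonal steps, sqrt(2) px for diagonal steps (the convention of
#' standard skeleton-analysis tools), times the pixel size. Branched
#' skeletons sum all branch lengths; junction pixels are counted once. The
#' step set is the minimum spanning forest of the pixel-adjacency graph, so
#' corner pixels are connected through orthogonal steps rather than diagonal
#' shortcuts and the result does not depend on traversal order.
#'
#' @param skeleton A [skeleton_image()].
#' @return Length in micrometres.
#' @export
skeleton_length_um <- function(skeleton) {
  stopifnot(inherits(skeleton, "spq_skeleton"))
  px <- skeleton$pixels
  fg <- which(px == 1, arr.ind = TRUE)
  n <- nrow(fg)
  if (n == 0) stop("empty skeleton")
  if (n == 1) return(0)
  key <- (fg[, 1] - 1) * (ncol(px) + 2L) + fg[, 2]  # +2 guards edge wrap
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  wts <- c(1, 1, sqrt(2), sqrt(2))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(4)) {
    nk <- (fg[, 1] + offs[k, 1] - 1) * (ncol(px) + 2L) + (fg[, 2] + offs[k, 2])
    hit <- match(nk, key)
    ok <- !is.na(hit)
    from <- c(from, which(ok)); to <- c(to, hit[ok])
    w <- c(w, rep(wts[k], sum(ok)))
  }
  if (length(from) == 0) return(0)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  sum(igraph::E(mst)$weight) * skeleton$pixel_size_um
}

#' Restrict a projection to a mask
#'
#' Pixels outside the mask foreground are set to zero; pixels inside are
#' unchanged.
#'
#' @param proj A [projection()].
#' @param mask An `spq_mask` of the same shape.
#' @return A [projection()].
#' @export
apply_mask <- function(proj, mask) {
  stopifnot(inherits(proj, "spq_projection"), inherits(mask, "spq_mask"))
  if (!identical(dim(proj$pixels), dim(mask$pixels))) {
    stop("projection and mask shapes differ")
  }
  out <- proj$pixels * mask$pixels
  projection(out, pixel_size_um = proj$pixel_size_um,
             unit_scaled = proj$unit_scaled, bit_depth = proj$bit_depth)
}

#' Read or write skeleton/mask images as PNG
#'
#' Binary images are stored white-on-black, as produced by drawing tools.
#'
#' @param path PNG path.
#' @param pixel_size_um Micrometres per pixel for the returned object.
#' @return `read_skeleton_png()` returns an `spq_skeleton`;
#'   `read_mask_png()` an `spq_mask`.
#' @export
read_skeleton_png <- function(path, pixel_size_um = 0.0526) {
  px <- png_binary(path)
  skeleton_image(px, pixel_size_um = pixel_size_um)
}

#' @rdname read_skeleton_png
#' @export
read_mask_png <- function(path, pixel_size_um = 0.0526) {
  roi_mask(png_binary(path), pixel_size_um = pixel_size_um)
}

#' @rdname read_skeleton_png
#' @param x An `spq_skeleton` or `spq_mask`.
#' @export
write_binary_png <- function(x, path) {
  png::writePNG(x$pixels, path)
  invisible(path)
}

png_binary <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.numeric(img > 0.5), nrow(img), ncol(img))
}
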