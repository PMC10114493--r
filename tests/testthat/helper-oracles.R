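# fixtures and independent oracles used across the suite

make_proj <- function(mat, pixel_size_um = 0.0526) {
  projection(mat, pixel_size_um = pixel_size_um, unit_scaled = TRUE)
}

full_mask <- function(nr, nc, pixel_size_um = 0.0526) {
  roi_mask(matrix(1, nr, nc), pixel_size_um = pixel_size_um)
}

# recursive flood-fill component counter/labeller, independent of the
# package's union-find/igraph route
flood_fill_label <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  cur <- 0L
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    if (m[y, x] != 0 && lab[y, x] == 0L) {
      cur <- cur + 1L
      queue <- list(c(y, x))
      lab[y, x] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (o in offs) {
          yy <- p[1] + o[1]; xx <- p[2] + o[2]
          if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc &&
              m[yy, xx] != 0 && lab[yy, xx] == 0L) {
            lab[yy, xx] <- cur
            queue[[length(queue) + 1]] <- c(yy, xx)
          }
        }
      }
    }
  }
  lab
}

# vectorised min-label propagation over ALL 4x4 binary patterns at once;
# returns component count per pattern. Independent of both other routes.
all_patterns_4x4 <- function() {
  bits <- t(sapply(0:65535, function(k) as.integer(intToBits(k)[1:16])))
  array(bits, dim = c(65536L, 4L, 4L))
}

propagate_counts <- function(pats, connectivity = 8L) {
  n <- dim(pats)[1]
  lab <- array(rep(1:16, each = n), dim = dim(pats)) * pats
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  shift_lab <- function(L, o) {
    out <- array(Inf, dim = dim(L))
    ys <- seq_len(4) + o[1]; xs <- seq_len(4) + o[2]
    oky <- ys >= 1 & ys <= 4; okx <- xs >= 1 & xs <= 4
    out[, which(oky), which(okx)] <- L[, ys[oky], xs[okx]]
    out
  }
  lab[lab == 0] <- Inf
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_lab(lab, o))
    new[pats == 0] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  counts <- integer(n)
  flat <- matrix(lab, n, 16)
  for (i in seq_len(n)) {
    v <- flat[i, ]
    counts[i] <- length(unique(v[is.finite(v)]))
  }
  counts
}

# label all 4x4 patterns with the package implementation in one call by
# tiling them into a large image separated by background gaps
tiled_counts <- function(pats, connectivity = 8L) {
  n <- dim(pats)[1]
  per_row <- 256L
  rows <- ceiling(n / per_row)
  big <- matrix(0, rows * 6, per_row * 6)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% per_row; c_ <- (i - 1) %% per_row
    big[(r * 6 + 1):(r * 6 + 4), (c_ * 6 + 1):(c_ * 6 + 4)] <- pats[i, , ]
  }
  lab <- label_components(big, connectivity)
  counts <- integer(n)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% per_row; c_ <- (i - 1) %% per_row
    v <- lab[(r * 6 + 1):(r * 6 + 4), (c_ * 6 + 1):(c_ * 6 + 4)]
    counts[i] <- length(unique(v[v > 0]))
  }
  counts
}

# partition equality of two labelings (same pixel grouping up to renaming)
same_partition <- function(a, b) {
  fa <- a[a > 0 | b > 0]; fb <- b[a > 0 | b > 0]
  if (any(fa == 0) || any(fb == 0)) return(FALSE)
  length(unique(paste(fa, fb))) == length(unique(fa)) &&
    length(unique(paste(fa, fb))) == length(unique(fb))
}
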