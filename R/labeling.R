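# Connected-component labeling of binary membership images at 4- or
# 8-connectivity. Built on a vectorised pixel-adjacency edge list resolved
# with igraph; labels are assigned in raster order of each component's first
# pixel so output is deterministic.

#' Label connected components of a binary image
#'
#' @param membership Binary matrix (logical or 0/1), foreground = member.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components
#'   numbered 1..n in raster order of first occurrence.
#' @export
label_components <- function(membership, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- membership != 0
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  fgi <- which(m)  # column-major linear indices
  n <- length(fgi)
  if (n == 0) return(lab)
  pos <- integer(nr * nc)
  pos[fgi] <- seq_len(n)
  ys <- ((fgi - 1L) %% nr) + 1L
  xs <- ((fgi - 1L) %/% nr) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    ny <- ys + o[1]; nx <- xs + o[2]
    ok <- ny >= 1L & ny <= nr & nx >= 1L & nx <= nc
    ni <- (nx[ok] - 1L) * nr + ny[ok]
    hit <- pos[ni]
    sel <- hit > 0L
    from <- c(from, pos[fgi[ok]][sel])
    to <- c(to, hit[sel])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    comp <- igraph::components(g)$membership
  } else {
    comp <- seq_len(n)
  }
  # renumber in raster (row-major) order of first appearance
  ord <- order(ys, xs)
  relab <- integer(max(comp))
  nxt <- 0L
  for (i in ord) {
    c_ <- comp[i]
    if (relab[c_] == 0L) { nxt <- nxt + 1L; relab[c_] <- nxt }
  }
  lab[fgi] <- relab[comp]
  lab
}
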