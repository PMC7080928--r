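# Low-level array helpers shared by segmentation and foci detection.
# Conventions: volumes are arrays with dim (nz, ny, nx), images are matrices
# with dim (ny, nx); all indices 1-based in R, reported coordinates are
# (z, y, x) voxel indices.

#' Neighbourhood offsets for a given 3D connectivity
#'
#' @param connectivity one of 6, 18, 26
#' @return integer matrix with columns (dz, dy, dx), one row per neighbour
#' @keywords internal
#' @noRd
conn_offsets_3d <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  l1 <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
    "6"  = l1 == 1,
    "18" = l1 <= 2,
    "26" = rep(TRUE, nrow(g)))
  g[keep, , drop = FALSE]
}

#' 8- or 4-neighbour offsets in 2D, columns (dy, dx)
#' @noRd
conn_offsets_2d <- function(connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  g <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 4) g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  g
}

#' Shift an array by an integer offset, filling exposed entries
#'
#' shift_array(a, s)[i] == a[i - s] where defined, `fill` elsewhere.
#' Works for 2D and 3D arrays.
#' @noRd
shift_array <- function(a, s, fill) {
  d <- dim(a)
  nd <- length(d)
  out <- array(fill, d)
  dst <- src <- vector("list", nd)
  for (k in seq_len(nd)) {
    dst[[k]] <- max(1L, 1L + s[k]):min(d[k], d[k] + s[k])
    src[[k]] <- max(1L, 1L - s[k]):min(d[k], d[k] - s[k])
    if (s[k] >= d[k] || -s[k] >= d[k]) return(out)
  }
  if (nd == 2) out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' In-bounds neighbours of a set of voxels
#'
#' @param coords integer matrix, one row per voxel, columns in array dim order
#' @param dims array dimensions
#' @param offsets offset matrix (same column order)
#' @return list with `coords` (matrix) and `from` (row index into input)
#' @noRd
neighbour_coords <- function(coords, dims, offsets) {
  n <- nrow(coords); k <- nrow(offsets); nd <- ncol(coords)
  rep_c <- coords[rep(seq_len(n), each = k), , drop = FALSE]
  rep_o <- offsets[rep(seq_len(k), times = n), , drop = FALSE]
  nc <- rep_c + rep_o
  ok <- rep(TRUE, nrow(nc))
  for (j in seq_len(nd)) ok <- ok & nc[, j] >= 1L & nc[, j] <= dims[j]
  list(coords = nc[ok, , drop = FALSE],
       from = rep(seq_len(n), each = k)[ok])
}

lin_index <- function(coords, dims) {
  # coords: matrix in dim order; returns 1-based linear indices
  idx <- coords[, 1]
  mult <- 1
  for (j in seq_along(dims)[-1]) {
    mult <- mult * dims[j - 1]
    idx <- idx + (coords[, j] - 1L) * mult
  }
  idx
}

#' Connected-component labelling of a logical array (frontier BFS)
#'
#' @param mask logical array (2D or 3D)
#' @param offsets neighbour offsets in dim order
#' @return integer array of labels (0 background), consecutive from 1
#' @noRd
label_components <- function(mask, offsets) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  todo <- which(mask)
  if (length(todo) == 0) return(lab)
  inmask <- array(FALSE, dims); inmask[todo] <- TRUE
  nextlab <- 0L
  remaining <- todo
  visited <- array(FALSE, dims)
  while (length(remaining) > 0) {
    seed <- remaining[1]
    nextlab <- nextlab + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- nextlab
    while (length(frontier) > 0) {
      crd <- arrayInd(frontier, dims)
      nb <- neighbour_coords(crd, dims, offsets)
      if (nrow(nb$coords) == 0) break
      ni <- lin_index(nb$coords, dims)
      ni <- unique(ni[inmask[ni] & !visited[ni]])
      if (length(ni) == 0) break
      visited[ni] <- TRUE
      lab[ni] <- nextlab
      frontier <- ni
    }
    remaining <- remaining[!visited[remaining]]
  }
  lab
}

#' Flood fill from seeds over a predicate array
#'
#' Returns linear indices of the connected region of `ok` voxels containing
#' the seeds. `cap`: stop once more than `cap` voxels collected (the result
#' then carries attribute `truncated = TRUE`).
#' @noRd
flood_fill <- function(ok, seeds, offsets, cap = Inf, seen = NULL) {
  dims <- dim(ok)
  seeds <- unique(seeds[ok[seeds]])
  if (length(seeds) == 0) return(integer(0))
  # `seen` may be a shared scratch logical array (all FALSE on entry); it is
  # reset to FALSE on the touched indices before returning, so repeated calls
  # avoid re-allocating a full-volume array.
  if (is.null(seen)) seen <- array(FALSE, dims)
  region <- integer(0)
  frontier <- seeds
  seen[frontier] <- TRUE
  truncated <- FALSE
  while (length(frontier) > 0) {
    region <- c(region, frontier)
    if (length(region) > cap) { truncated <- TRUE; break }
    crd <- arrayInd(frontier, dims)
    nb <- neighbour_coords(crd, dims, offsets)
    if (nrow(nb$coords) == 0) break
    ni <- unique(lin_index(nb$coords, dims))
    ni <- ni[ok[ni] & !seen[ni]]
    if (length(ni) == 0) break
    seen[ni] <- TRUE
    frontier <- ni
  }
  attr(region, "truncated") <- truncated
  region
}
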