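# Independent brute-force oracles and fixture builders. These deliberately
# use naive loop implementations, separate from the package's vectorized
# code paths.

# Otsu: exhaustive search over all splits of the observed values; returns
# the midpoint between the two classes at the best split
bf_otsu <- function(img) {
  vals <- sort(unique(as.vector(img)))
  stopifnot(length(vals) >= 2)
  v <- as.vector(img)
  best <- -Inf; best_i <- 1
  for (i in seq_len(length(vals) - 1)) {
    lo <- v[v <= vals[i]]; hi <- v[v > vals[i]]
    bcv <- (length(lo) / length(v)) * (length(hi) / length(v)) *
      (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_i <- i }
  }
  (vals[best_i] + vals[best_i + 1]) / 2
}

# sliding binary median over the in-bounds radius-r disk (median of 0/1
# values; exact .5 ties binarized to background)
bf_median_disk <- function(mask, r = 2) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- mask
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > r^2) next
      yy <- y + dy; xx <- x + dx
      if (yy < 1 || yy > ny || xx < 1 || xx > nx) next
      vals <- c(vals, mask[yy, xx])
    }
    out[y, x] <- stats::median(vals) > 0.5
  }
  out
}

# fill holes by iterative dilation of border-connected background
# (4-connectivity), implemented with whole-matrix shifts
bf_fill_holes <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  bg <- !mask
  reach <- matrix(FALSE, ny, nx)
  reach[1, ] <- bg[1, ]; reach[ny, ] <- bg[ny, ]
  reach[, 1] <- bg[, 1]; reach[, nx] <- bg[, nx]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-ny, ]
    grown[-ny, ] <- grown[-ny, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -nx]
    grown[, -nx] <- grown[, -nx] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  mask | (!reach & bg)
}

bf_neighbours <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[rowSums(abs(g)) > 0, ]
  l1 <- rowSums(abs(g))
  if (connectivity == 6) g <- g[l1 == 1, ]
  if (connectivity == 18) g <- g[l1 <= 2, ]
  as.matrix(g)
}

# exhaustive plateau-aware local maxima: equal-value connected components
# with all outside neighbours strictly lower; the global-minimum plateau is
# never a maximum. Returns a list of sorted linear-index vectors.
bf_local_maxima <- function(vol, connectivity = 26) {
  d <- dim(vol)
  offs <- bf_neighbours(connectivity)
  seen <- array(FALSE, d)
  vmin <- min(vol)
  res <- list()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    if (seen[z, y, x]) next
    val <- vol[z, y, x]
    # BFS over the equal-value plateau
    comp <- matrix(c(z, y, x), ncol = 3)
    queue <- list(c(z, y, x))
    seen[z, y, x] <- TRUE
    is_max <- TRUE
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(offs))) {
        nz <- c0[1] + offs[i, 1]; nyy <- c0[2] + offs[i, 2]; nxx <- c0[3] + offs[i, 3]
        if (nz < 1 || nz > d[1] || nyy < 1 || nyy > d[2] || nxx < 1 || nxx > d[3]) next
        nv <- vol[nz, nyy, nxx]
        if (nv > val) is_max <- FALSE
        if (nv == val && !seen[nz, nyy, nxx]) {
          seen[nz, nyy, nxx] <- TRUE
          comp <- rbind(comp, c(nz, nyy, nxx))
          queue[[length(queue) + 1]] <- c(nz, nyy, nxx)
        }
      }
    }
    if (is_max && val != vmin) {
      idx <- sort(comp[, 1] + (comp[, 2] - 1) * d[1] + (comp[, 3] - 1) * d[1] * d[2])
      res[[length(res) + 1]] <- idx
    }
  }
  res
}

# shell/ball background by explicit enumeration
bf_shell_stat <- function(vol, centre, r = 6, tol = 0.5, mode = "shell",
                          stat = "mean") {
  d <- dim(vol)
  vals <- c()
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    dd <- sqrt((z - centre[1])^2 + (y - centre[2])^2 + (x - centre[3])^2)
    ok <- if (mode == "ball") dd <= r + tol else dd >= r - tol && dd <= r + tol
    if (ok) vals <- c(vals, vol[z, y, x])
  }
  if (length(vals) == 0) stop("empty shell")
  if (stat == "mean") mean(vals) else stats::median(vals)
}

# naive threshold flood fill from seeds
bf_flood <- function(vol, seeds, thr, connectivity = 26) {
  d <- dim(vol)
  offs <- bf_neighbours(connectivity)
  seen <- array(FALSE, d)
  crd <- arrayInd(seeds, d)
  queue <- lapply(seq_len(nrow(crd)), function(i) crd[i, ])
  queue <- Filter(function(c0) vol[c0[1], c0[2], c0[3]] >= thr, queue)
  for (c0 in queue) seen[c0[1], c0[2], c0[3]] <- TRUE
  out <- c()
  while (length(queue)) {
    c0 <- queue[[1]]; queue <- queue[-1]
    out <- c(out, c0[1] + (c0[2] - 1) * d[1] + (c0[3] - 1) * d[1] * d[2])
    for (i in seq_len(nrow(offs))) {
      nz <- c0[1] + offs[i, 1]; ny <- c0[2] + offs[i, 2]; nx <- c0[3] + offs[i, 3]
      if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] || nx < 1 || nx > d[3]) next
      if (!seen[nz, ny, nx] && vol[nz, ny, nx] >= thr) {
        seen[nz, ny, nx] <- TRUE
        queue[[length(queue) + 1]] <- c(nz, ny, nx)
      }
    }
  }
  as.integer(sort(out))
}

# render an isotropic Gaussian focus into a volume (voxel-centre sampling)
add_gauss_fixture <- function(vol, cz, cy, cx, amp, sigma) {
  d <- dim(vol)
  for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
    vol[z, y, x] <- vol[z, y, x] +
      amp * exp(-((z - cz)^2 + (y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
  }
  vol
}

# binary disk image fixture
draw_disks <- function(ny, nx, centres, radius, value = 200, bg = 0) {
  img <- matrix(bg, ny, nx)
  for (k in seq_len(nrow(centres))) {
    for (y in 1:ny) for (x in 1:nx) {
      if ((y - centres[k, 1])^2 + (x - centres[k, 2])^2 <= radius^2)
        img[y, x] <- value
    }
  }
  img
}

# greedy one-to-one matching of detected foci to true centres
match_foci <- function(det, truth, max_dist = 4) {
  if (nrow(det) == 0 || nrow(truth) == 0)
    return(list(tp = 0, fp = nrow(det), fn = nrow(truth)))
  d2 <- outer(det$z, truth$cz, "-")^2 + outer(det$y, truth$cy, "-")^2 +
    outer(det$x, truth$cx, "-")^2
  md <- rep(FALSE, nrow(det)); mt <- rep(FALSE, nrow(truth))
  for (i in order(d2)) {
    if (d2[i] > max_dist^2) break
    ri <- (i - 1) %% nrow(det) + 1; ci <- (i - 1) %/% nrow(det) + 1
    if (!md[ri] && !mt[ci]) { md[ri] <- TRUE; mt[ci] <- TRUE }
  }
  list(tp = sum(md), fp = sum(!md), fn = sum(!mt))
}
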