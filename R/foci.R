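# 3D gamma-H2AX foci detection.
#
# A focus is a coherent (connectivity-connected) voxel region with exactly
# one local-maximum centre, where a centre is a single voxel or a plateau of
# contiguous equal-intensity voxels whose outside neighbours are all
# strictly lower. The background of each focus is estimated from the voxels
# at a 6-voxel (index-space) radius around its maximum; the region is grown
# from the maximum down to background + alpha * (peak - background); regions
# are retained only when strictly larger than `min_voxels` (8 for the liver
# protocol, 20 for testis).

#' Foci detection parameters
#'
#' @param min_voxels strict lower size bound: a region is reported iff it
#'   has more than `min_voxels` voxels (liver default 8; use 20 for testis)
#' @param background_radius_vox radius of the background shell in voxel
#'   index units (default 6)
#' @param connectivity 6, 18 or 26 (default 26)
#' @param growth_fraction alpha in (0, 1]: region threshold is
#'   `background + alpha * (peak - background)` (default 0.5)
#' @param multi_max_policy `"split"` (default) separates a region containing
#'   several maxima along intensity watershed lines seeded at the maxima;
#'   `"reject"` discards such regions
#' @param background_stat `"mean"` (default) or `"median"` over shell voxels
#' @param shell_tolerance half-width of the shell in voxels (default 0.5:
#'   voxels at Euclidean distance within `radius +- 0.5`)
#' @param shell_mode `"shell"` (default) or `"ball"` (all voxels within
#'   `radius + tolerance`)
#' @return an object of class `foci_params`
#' @export
foci_params <- function(min_voxels = 8L, background_radius_vox = 6,
                        connectivity = 26L, growth_fraction = 0.5,
                        multi_max_policy = c("split", "reject"),
                        background_stat = c("mean", "median"),
                        shell_tolerance = 0.5,
                        shell_mode = c("shell", "ball")) {
  multi_max_policy <- match.arg(multi_max_policy)
  background_stat <- match.arg(background_stat)
  shell_mode <- match.arg(shell_mode)
  stopifnot(min_voxels >= 1, background_radius_vox >= 1,
            connectivity %in% c(6, 18, 26),
            growth_fraction > 0, growth_fraction <= 1)
  structure(list(min_voxels = as.integer(min_voxels),
                 background_radius_vox = background_radius_vox,
                 connectivity = as.integer(connectivity),
                 growth_fraction = growth_fraction,
                 multi_max_policy = multi_max_policy,
                 background_stat = background_stat,
                 shell_tolerance = shell_tolerance,
                 shell_mode = shell_mode),
            class = "foci_params")
}

#' Plateau-aware local maxima of a 3D volume
#'
#' A maximum is a maximal connected set of equal-intensity voxels all of
#' whose outside neighbours have strictly lower intensity (a single bright
#' voxel is the one-voxel case). Border voxels compare only their in-bounds
#' neighbours.
#'
#' @param volume 3D numeric array (dim `(nz, ny, nx)`)
#' @param connectivity 6, 18 or 26
#' @return list of maxima; each has `voxels` (linear indices of the plateau),
#'   `value` (the plateau intensity), `centroid` (z, y, x; mean of the
#'   plateau coordinates) and `rep` (z, y, x of the plateau voxel closest to
#'   the centroid)
#' @export
find_local_maxima_3d <- function(volume, connectivity = 26L) {
  local_maxima_internal(volume, connectivity, want_ptr = FALSE)$maxima
}

# shared implementation: local maxima plus (optionally) the steepest-ascent
# pointer of every voxel, computed in the same pass over the neighbour
# offsets
local_maxima_internal <- function(volume, connectivity, want_ptr = FALSE) {
  stopifnot(is.array(volume), length(dim(volume)) == 3)
  dims <- dim(volume)
  n <- prod(dims)
  volv <- as.vector(volume)
  offs <- conn_offsets_3d(connectivity)
  deltas <- offs[, 1] + offs[, 2] * dims[1] + offs[, 3] * dims[1] * dims[2]
  neigh_max <- rep(-Inf, n)
  ptr <- if (want_ptr) seq_len(n) else NULL
  best_val <- if (want_ptr) rep(-Inf, n) else NULL
  for (i in seq_len(nrow(offs))) {
    sv <- as.vector(shift_array(volume, offs[i, ], -Inf))
    neigh_max <- pmax(neigh_max, sv)
    if (want_ptr) {
      better <- sv > volv & sv > best_val
      if (any(better)) {
        w <- which(better)
        best_val[w] <- sv[w]
        ptr[w] <- w - deltas[i]   # shift by s puts a[i - s] at i
      }
    }
  }
  cand <- volv >= neigh_max
  # a plateau at the global minimum can never be a maximum: there is no
  # strictly lower intensity for its neighbours to take (the constant
  # volume has no maxima)
  vmin <- min(volv)
  p_idx <- which(cand & volv != vmin)
  if (length(p_idx) == 0)
    return(list(maxima = list(), ptr = ptr, dims = dims))
  # adjacent candidates always share the same intensity, so candidate
  # plateaus are plain connected components of the (sparse) candidate set;
  # a component is a maximum iff no member has an equal-valued non-candidate
  # neighbour (such a neighbour belongs to the same intensity plateau but
  # has a strictly greater neighbour of its own)
  comp <- group_sparse_components(p_idx, dims, offs, deltas)
  zc <- ((p_idx - 1L) %% dims[1]) + 1L
  yc <- (((p_idx - 1L) %/% dims[1]) %% dims[2]) + 1L
  xc <- ((p_idx - 1L) %/% (dims[1] * dims[2])) + 1L
  bad_comp <- rep(FALSE, max(comp))
  for (oi in seq_len(nrow(offs))) {
    okf <- zc + offs[oi, 1] >= 1L & zc + offs[oi, 1] <= dims[1] &
           yc + offs[oi, 2] >= 1L & yc + offs[oi, 2] <= dims[2] &
           xc + offs[oi, 3] >= 1L & xc + offs[oi, 3] <= dims[3]
    nb <- p_idx[okf] + deltas[oi]
    viol <- volv[nb] == volv[p_idx[okf]] & !cand[nb]
    if (any(viol)) bad_comp[unique(comp[okf][viol])] <- TRUE
  }
  maxima <- vector("list", sum(!bad_comp))
  g_out <- 0L
  for (g in which(!bad_comp)) {
    sel <- comp == g
    vox <- p_idx[sel]
    cen <- c(mean(zc[sel]), mean(yc[sel]), mean(xc[sel]))
    if (length(vox) == 1) {
      rp <- cen
    } else {
      d2 <- (zc[sel] - cen[1])^2 + (yc[sel] - cen[2])^2 + (xc[sel] - cen[3])^2
      k <- which.min(d2)
      rp <- c(zc[sel][k], yc[sel][k], xc[sel][k])
    }
    g_out <- g_out + 1L
    maxima[[g_out]] <- list(voxels = vox, value = volv[vox[1]],
                            centroid = cen, rep = rp)
  }
  list(maxima = maxima, ptr = ptr, dims = dims)
}

# connected components of a sparse voxel set (sorted linear indices)
group_sparse_components <- function(idx, dims, offs, deltas) {
  m <- length(idx)
  parent <- seq_len(m)
  findp <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  zc <- ((idx - 1L) %% dims[1]) + 1L
  yc <- (((idx - 1L) %/% dims[1]) %% dims[2]) + 1L
  xc <- ((idx - 1L) %/% (dims[1] * dims[2])) + 1L
  for (oi in seq_len(nrow(offs))) {
    okf <- zc + offs[oi, 1] >= 1L & zc + offs[oi, 1] <= dims[1] &
           yc + offs[oi, 2] >= 1L & yc + offs[oi, 2] <= dims[2] &
           xc + offs[oi, 3] >= 1L & xc + offs[oi, 3] <= dims[3]
    nb <- idx[okf] + deltas[oi]
    pos <- findInterval(nb, idx)
    hit <- pos > 0L & idx[pmax(pos, 1L)] == nb
    a <- which(okf)[hit]; b <- pos[hit]
    for (k in seq_along(a)) {
      ra <- findp(a[k]); rb <- findp(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(m), findp, integer(1))
  match(roots, unique(roots))
}

shell_offset_cache <- new.env(parent = emptyenv())

shell_offsets <- function(radius, tolerance, mode) {
  key <- paste(radius, tolerance, mode, sep = "|")
  hit <- shell_offset_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- ceiling(radius + tolerance)
  g <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  d <- sqrt(rowSums(g^2))
  keep <- if (mode == "ball") d <= radius + tolerance
          else d >= radius - tolerance & d <= radius + tolerance
  out <- g[keep, , drop = FALSE]
  shell_offset_cache[[key]] <- out
  out
}

#' Background level around a maximum
#'
#' The background is the `background_stat` (mean or median) of the
#' intensities of all in-bounds voxels whose index-space Euclidean distance
#' from the maximum centroid lies within `radius +- tolerance` (or the whole
#' ball in `"ball"` mode). Near the volume border only the in-bounds part of
#' the shell is used.
#'
#' @param volume 3D numeric array
#' @param maximum a maximum from [find_local_maxima_3d()], or a length-3
#'   numeric `(z, y, x)` centroid
#' @param params a [foci_params()]
#' @return background intensity (numeric scalar)
#' @export
background_at_maximum <- function(volume, maximum, params = foci_params()) {
  centroid <- if (is.list(maximum)) maximum$centroid else as.numeric(maximum)
  dims <- dim(volume)
  r <- params$background_radius_vox; tol <- params$shell_tolerance
  if (all(centroid == round(centroid))) {
    offs <- shell_offsets(r, tol, params$shell_mode)
    z <- centroid[1] + offs[, 1]; y <- centroid[2] + offs[, 2]
    x <- centroid[3] + offs[, 3]
  } else {
    b <- ceiling(r + tol)
    zz <- max(1, floor(centroid[1] - b)):min(dims[1], ceiling(centroid[1] + b))
    yy <- max(1, floor(centroid[2] - b)):min(dims[2], ceiling(centroid[2] + b))
    xx <- max(1, floor(centroid[3] - b)):min(dims[3], ceiling(centroid[3] + b))
    g <- expand.grid(z = zz, y = yy, x = xx)
    d <- sqrt((g$z - centroid[1])^2 + (g$y - centroid[2])^2 + (g$x - centroid[3])^2)
    keep <- if (params$shell_mode == "ball") d <= r + tol
            else d >= r - tol & d <= r + tol
    z <- g$z[keep]; y <- g$y[keep]; x <- g$x[keep]
  }
  ok <- z >= 1 & z <= dims[1] & y >= 1 & y <= dims[2] & x >= 1 & x <= dims[3]
  if (!any(ok)) stop("degenerate shell: no in-bounds voxels at the background radius")
  idx <- z[ok] + (y[ok] - 1) * dims[1] + (x[ok] - 1) * dims[1] * dims[2]
  if (params$background_stat == "mean") mean(volume[idx]) else stats::median(volume[idx])
}

#' Grow the region of a focus from its maximum
#'
#' Returns the connectivity-connected component, containing the maximum, of
#' voxels with intensity at or above
#' `background + growth_fraction * (peak - background)`. With
#' `growth_fraction = 1` this is the plateau itself. Growth can be clipped
#' to a mask.
#'
#' @param volume 3D numeric array
#' @param maximum a maximum from [find_local_maxima_3d()]
#' @param background background level (see [background_at_maximum()])
#' @param params a [foci_params()]
#' @param mask optional logical/label array of the same dim; growth is
#'   restricted to nonzero mask voxels
#' @return sorted linear voxel indices of the region
#' @export
grow_focus_region <- function(volume, maximum, background,
                              params = foci_params(), mask = NULL) {
  peak <- maximum$value
  if (peak <= background) stop("peak must exceed background")
  thr <- background + params$growth_fraction * (peak - background)
  ok <- volume >= thr
  if (!is.null(mask)) ok <- ok & (mask > 0)
  sort(as.integer(flood_fill(ok, maximum$voxels, conn_offsets_3d(params$connectivity))))
}

#' Detect gamma-H2AX foci in a 3D volume
#'
#' For each local maximum (restricted to `mask` when given): estimate the
#' shell background, grow the region at the `growth_fraction` level, apply
#' the strict size filter (`size > min_voxels`), and enforce the
#' single-maximum rule. Under `multi_max_policy = "split"` (default) every
#' voxel is first assigned to the basin of the maximum reached by steepest
#' ascent (an intensity watershed seeded at all maxima), and the region of
#' a focus is the connected part of its own basin above its growth
#' threshold — so a region never contains a second maximum, and noise
#' maxima fragment into sub-threshold pieces. Under `"reject"`, regions are
#' grown without basin restriction and any region containing more than one
#' maximum is discarded. Maxima whose background shell is degenerate are
#' skipped with a warning.
#'
#' @param volume 3D numeric array (the gamma-H2AX channel)
#' @param params a [foci_params()]
#' @param mask optional 3D label array (e.g. from [extrude_labels_to_3d()]);
#'   detection and growth are restricted to nonzero labels
#' @param mode analysis mode recorded in the result: `"per_nucleus"` (liver)
#'   or `"per_roi"` (testis)
#' @return an object of class `foci_set`: list with `foci` (tibble: id, z,
#'   y, x, peak, background, size_vox, nucleus_id), `regions` (list of
#'   linear voxel index vectors, pairwise disjoint), `params`, `dims`,
#'   `mode`
#' @export
detect_foci <- function(volume, params = foci_params(), mask = NULL,
                        mode = c("per_nucleus", "per_roi")) {
  mode <- match.arg(mode)
  dims <- dim(volume)
  offs <- conn_offsets_3d(params$connectivity)
  mx <- local_maxima_internal(volume, params$connectivity,
                              want_ptr = params$multi_max_policy == "split")
  maxima <- mx$maxima
  if (!is.null(mask)) {
    keep <- vapply(maxima, function(m) {
      rp <- m$rep
      mask[rp[1], rp[2], rp[3]] > 0
    }, logical(1))
    maxima <- maxima[keep]
  }
  if (length(maxima) == 0) return(empty_foci_set(params, dims, mode))

  # vectorized shell background for integer-centroid maxima
  bg <- rep(NA_real_, length(maxima))
  int_cen <- vapply(maxima, function(m) all(m$centroid == round(m$centroid)),
                    logical(1))
  if (any(int_cen)) {
    so <- shell_offsets(params$background_radius_vox, params$shell_tolerance,
                        params$shell_mode)
    cen <- t(vapply(maxima[int_cen], `[[`, numeric(3), "centroid"))
    bg[int_cen] <- shell_stat_batch(volume, cen, so, params$background_stat)
  }
  for (i in which(!int_cen)) {
    bg[i] <- tryCatch(background_at_maximum(volume, maxima[[i]], params),
                      error = function(e) NA_real_)
  }
  if (any(is.na(bg))) {
    warning(sum(is.na(bg)), " maxima skipped (degenerate background shell)")
  }

  zc <- rep.int(seq_len(dims[1]), dims[2] * dims[3])
  yc <- rep.int(rep(seq_len(dims[2]), each = dims[1]), dims[3])
  xc <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
  deltas <- offs[, 1] + offs[, 2] * dims[1] + offs[, 3] * dims[1] * dims[2]
  maskv <- if (!is.null(mask)) as.vector(mask) > 0 else NULL
  volv <- as.vector(volume)
  basin <- if (params$multi_max_policy == "split")
    basin_assignment(volume, maxima, mx$ptr, offs, deltas, domain = maskv)
  else NULL
  stamp <- integer(prod(dims))
  cur <- 0L

  # connected flood from the maximum over voxels >= thr (optionally
  # restricted to the maximum's own basin and to the mask), with a size cap
  # so sub-threshold noise maxima are rejected cheaply; the cap sits exactly
  # at the strict > min_voxels retention rule and full regions are
  # recomputed for retained foci only
  flood_local <- function(seeds, thr, cap, basin_id = NULL) {
    cur <<- cur + 1L
    frontier <- seeds
    if (!is.null(basin_id)) frontier <- frontier[basin[frontier] == basin_id]
    if (length(frontier) == 0) return(structure(integer(0), truncated = FALSE))
    stamp[frontier] <<- cur
    region <- integer(0)
    truncated <- FALSE
    while (length(frontier)) {
      region <- c(region, frontier)
      if (length(region) > cap) { truncated <- TRUE; break }
      nxt <- integer(0)
      for (oi in seq_along(deltas)) {
        okf <- zc[frontier] + offs[oi, 1] >= 1L & zc[frontier] + offs[oi, 1] <= dims[1] &
               yc[frontier] + offs[oi, 2] >= 1L & yc[frontier] + offs[oi, 2] <= dims[2] &
               xc[frontier] + offs[oi, 3] >= 1L & xc[frontier] + offs[oi, 3] <= dims[3]
        ni <- frontier[okf] + deltas[oi]
        ni <- ni[stamp[ni] != cur & volv[ni] >= thr]
        if (!is.null(basin_id) && length(ni)) ni <- ni[basin[ni] == basin_id]
        if (!is.null(maskv) && length(ni)) ni <- ni[maskv[ni]]
        if (length(ni)) { stamp[ni] <<- cur; nxt <- c(nxt, ni) }
      }
      frontier <- unique(nxt)
    }
    attr(region, "truncated") <- truncated
    region
  }

  foci <- list()
  if (params$multi_max_policy == "split") {
    for (i in seq_along(maxima)) {
      if (is.na(bg[i])) next
      peak <- maxima[[i]]$value
      if (peak <= bg[i]) next
      thr <- bg[i] + params$growth_fraction * (peak - bg[i])
      probe <- flood_local(maxima[[i]]$voxels, thr, cap = params$min_voxels,
                           basin_id = i)
      if (!attr(probe, "truncated")) next   # size <= min_voxels: rejected
      region <- flood_local(maxima[[i]]$voxels, thr, cap = Inf, basin_id = i)
      foci[[length(foci) + 1L]] <- list(maximum = maxima[[i]],
                                        background = bg[i],
                                        region = sort(as.integer(region)))
    }
  } else {
    # reject mode: grow without basin restriction; discard regions holding
    # more than one distinct maximum
    in_max <- integer(prod(dims))
    for (i in seq_along(maxima)) in_max[maxima[[i]]$voxels] <- i
    for (i in seq_along(maxima)) {
      if (is.na(bg[i])) next
      peak <- maxima[[i]]$value
      if (peak <= bg[i]) next
      thr <- bg[i] + params$growth_fraction * (peak - bg[i])
      region <- flood_local(maxima[[i]]$voxels, thr, cap = Inf)
      if (length(region) <= params$min_voxels) next
      held <- unique(in_max[region]); held <- held[held > 0]
      if (length(held) > 1) next
      foci[[length(foci) + 1L]] <- list(maximum = maxima[[i]],
                                        background = bg[i],
                                        region = sort(as.integer(region)))
    }
  }
  build_foci_set(foci, params, dims, mode)
}

# steepest-ascent basin of every voxel: the precomputed pointer to the
# strictly greater neighbour of highest intensity is resolved by pointer
# doubling; terminal plateau voxels inherit the id of their maximum, and
# saddle plateaus are resolved by sparse propagation passes from
# equal-or-greater neighbours. Voxels whose ascent ends in no maximum (and
# cannot adopt one) keep basin 0.
basin_assignment <- function(volume, maxima, ptr, offs, deltas,
                             domain = NULL) {
  dims <- dim(volume)
  n <- prod(dims)
  volv <- as.vector(volume)
  repeat {
    p2 <- ptr[ptr]
    if (identical(p2, ptr)) break
    ptr <- p2
  }
  term_map <- integer(n)
  for (i in seq_along(maxima)) term_map[maxima[[i]]$voxels] <- i
  basin <- term_map[ptr]
  unres <- which(basin == 0L)
  if (!is.null(domain)) unres <- unres[domain[unres]]
  for (pass in 1:4) {
    if (length(unres) == 0) break
    zc <- ((unres - 1L) %% dims[1]) + 1L
    yc <- (((unres - 1L) %/% dims[1]) %% dims[2]) + 1L
    xc <- ((unres - 1L) %/% (dims[1] * dims[2])) + 1L
    adopted <- integer(length(unres))
    adopted_val <- rep(-Inf, length(unres))
    for (oi in seq_len(nrow(offs))) {
      okf <- zc + offs[oi, 1] >= 1L & zc + offs[oi, 1] <= dims[1] &
             yc + offs[oi, 2] >= 1L & yc + offs[oi, 2] <= dims[2] &
             xc + offs[oi, 3] >= 1L & xc + offs[oi, 3] <= dims[3]
      nb <- unres[okf] + deltas[oi]
      take <- basin[nb] > 0L & volv[nb] >= volv[unres[okf]] &
        volv[nb] > adopted_val[okf]
      if (any(take)) {
        w <- which(okf)[take]
        adopted[w] <- basin[nb[take]]
        adopted_val[w] <- volv[nb[take]]
      }
    }
    newly <- adopted > 0L
    if (!any(newly)) break
    basin[unres[newly]] <- adopted[newly]
    unres <- unres[!newly]
  }
  basin
}

empty_foci_set <- function(params, dims, mode) {
  structure(list(
    foci = tibble::tibble(id = integer(0), z = numeric(0), y = numeric(0),
                          x = numeric(0), peak = numeric(0),
                          background = numeric(0), size_vox = integer(0),
                          nucleus_id = integer(0)),
    regions = list(), params = params, dims = dims, mode = mode),
    class = "foci_set")
}

build_foci_set <- function(foci, params, dims, mode) {
  if (length(foci) == 0) return(empty_foci_set(params, dims, mode))
  tb <- tibble::tibble(
    id = seq_along(foci),
    z = vapply(foci, function(f) f$maximum$centroid[1], numeric(1)),
    y = vapply(foci, function(f) f$maximum$centroid[2], numeric(1)),
    x = vapply(foci, function(f) f$maximum$centroid[3], numeric(1)),
    peak = vapply(foci, function(f) f$maximum$value, numeric(1)),
    background = vapply(foci, `[[`, numeric(1), "background"),
    size_vox = vapply(foci, function(f) length(f$region), integer(1)),
    nucleus_id = rep(0L, length(foci)))
  structure(list(foci = tb,
                 regions = lapply(foci, `[[`, "region"),
                 params = params, dims = dims, mode = mode),
            class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("foci_set: %d foci (%s mode, min_voxels = %d)\n",
              nrow(x$foci), x$mode, x$params$min_voxels))
  invisible(x)
}

# batch shell statistic at integer-centroid positions
shell_stat_batch <- function(volume, centres, offs, stat) {
  dims <- dim(volume)
  n <- nrow(centres); k <- nrow(offs)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / k))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    idx <- s:e
    z <- outer(centres[idx, 1], offs[, 1], "+")
    y <- outer(centres[idx, 2], offs[, 2], "+")
    x <- outer(centres[idx, 3], offs[, 3], "+")
    ok <- z >= 1 & z <= dims[1] & y >= 1 & y <= dims[2] & x >= 1 & x <= dims[3]
    li <- z + (y - 1) * dims[1] + (x - 1) * dims[1] * dims[2]
    vals <- matrix(NA_real_, length(idx), k)
    vals[ok] <- volume[li[ok]]
    out[idx] <- if (stat == "mean") rowMeans(vals, na.rm = TRUE)
                else apply(vals, 1, stats::median, na.rm = TRUE)
  }
  out
}

#' Assign detected foci to nuclei and count per nucleus
#'
#' A focus belongs to nucleus `k` iff its maximum voxel carries label `k` in
#' the 3D label volume. Counts are emitted for every label, including
#' zero-count nuclei (required for zero-foci fractions). Foci outside all
#' labels keep `nucleus_id = 0` and are excluded from the per-nucleus
#' counts.
#'
#' @param fociset a [detect_foci()] result
#' @param label_volume 3D integer label array (see [extrude_labels_to_3d()])
#' @return list with `fociset` (nucleus ids filled in) and `counts` (tibble:
#'   nucleus_id, n_foci — one row per label in the volume)
#' @export
assign_foci_to_nuclei <- function(fociset, label_volume) {
  stopifnot(inherits(fociset, "foci_set"),
            all(dim(label_volume) == fociset$dims))
  tb <- fociset$foci
  if (nrow(tb)) {
    rep_z <- round(tb$z); rep_y <- round(tb$y); rep_x <- round(tb$x)
    idx <- rep_z + (rep_y - 1) * fociset$dims[1] +
      (rep_x - 1) * fociset$dims[1] * fociset$dims[2]
    tb$nucleus_id <- as.integer(label_volume[idx])
  }
  fociset$foci <- tb
  k <- max(label_volume)
  counts <- tibble::tibble(
    nucleus_id = seq_len(k),
    n_foci = if (k > 0)
      as.integer(tabulate(tb$nucleus_id[tb$nucleus_id > 0], nbins = k))
    else integer(0))
  list(fociset = fociset, counts = counts)
}

#' Average foci per nucleus within manual ROIs (testis mode)
#'
#' Implements the testis protocol: foci are detected across the whole ROI
#' volume of the gamma-H2AX channel and the rate is the total focus count
#' divided by the number of cell nuclei in the ROI.
#'
#' @param volume 3D gamma-H2AX array
#' @param rois a [roi_set()] with `nucleus_counts` set
#' @param params a [foci_params()]; the testis default size filter is
#'   `min_voxels = 20`
#' @return tibble with one row per ROI: roi, n_foci, n_nuclei,
#'   foci_per_nucleus
#' @export
foci_per_nucleus_roi <- function(volume, rois, params = foci_params(min_voxels = 20L)) {
  stopifnot(inherits(rois, "roi_set"))
  if (is.null(rois$nucleus_counts)) stop("roi_set must carry nucleus_counts")
  nz <- dim(volume)[1]
  out <- lapply(sort(unique(rois$labels[rois$labels > 0])), function(r) {
    m3 <- extrude_labels_to_3d(rois$labels == r, nz)
    fs <- detect_foci(volume, params, mask = m3, mode = "per_roi")
    nn <- rois$nucleus_counts[[as.character(r)]]
    if (is.null(nn)) nn <- rois$nucleus_counts[[r]]
    tibble::tibble(roi = r, n_foci = nrow(fs$foci), n_nuclei = nn,
                   foci_per_nucleus = nrow(fs$foci) / nn)
  })
  dplyr::bind_rows(out)
}
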