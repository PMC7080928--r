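# Synthetic two-channel CLSM stack generator with known ground truth.
#
# Emulates the two tissue morphologies analysed by the pipeline: liver
# fields with large round hepatocyte nuclei carrying bright heterochromatin
# speckles next to smaller elongated, homogeneously stained non-hepatocyte
# nuclei; and testis fields with round spermatogonia / primary spermatocyte
# nuclei. gamma-H2AX foci are isotropic Gaussians in voxel-index space with
# per-nucleus counts drawn from a zero-inflated Poisson (ZIP) law, matching
# the excess-zero count histograms seen in exposed tissue.

CELL_CLASSES <- c("hepatocyte", "non_hepatocyte", "spermatogonium",
                  "primary_spermatocyte")

default_class_params <- function() {
  list(
    hepatocyte = list(
      semi_xy = c(18, 24), axis_ratio = c(1.0, 1.15), semi_z = c(4, 6),
      n_speckles = c(4, 8), speckle_amp_frac = c(0.5, 0.8),
      speckle_sigma = c(1.5, 2.5), dapi_amp = c(100, 140)),
    non_hepatocyte = list(
      semi_xy = c(11, 15), axis_ratio = c(1.8, 2.4), semi_z = c(3, 4),
      n_speckles = c(0, 0), speckle_amp_frac = c(0, 0),
      speckle_sigma = c(1.5, 1.5), dapi_amp = c(100, 140)),
    spermatogonium = list(
      semi_xy = c(10, 13), axis_ratio = c(1.0, 1.2), semi_z = c(3, 5),
      n_speckles = c(0, 0), speckle_amp_frac = c(0, 0),
      speckle_sigma = c(1.5, 1.5), dapi_amp = c(100, 140)),
    primary_spermatocyte = list(
      semi_xy = c(13, 16), axis_ratio = c(1.0, 1.2), semi_z = c(4, 6),
      n_speckles = c(0, 0), speckle_amp_frac = c(0, 0),
      speckle_sigma = c(1.5, 1.5), dapi_amp = c(100, 140))
  )
}

#' Zero-inflation probability for a target zero-count fraction
#'
#' Under a ZIP(pi0, mu) law the zero fraction is
#' `pi0 + (1 - pi0) * exp(-mu)`; this solves for `pi0` given the target.
#'
#' @param zero_fraction desired probability of a zero count
#' @param mu Poisson mean of the non-inflated component
#' @return `pi0` in `[0, 1]`
#' @export
zip_pi0_for_zero_fraction <- function(zero_fraction, mu) {
  stopifnot(zero_fraction >= 0, zero_fraction <= 1, mu >= 0)
  p0 <- exp(-mu)
  if (zero_fraction < p0)
    stop("target zero fraction below the plain-Poisson floor exp(-mu)")
  (zero_fraction - p0) / (1 - p0)
}

#' Configuration for the synthetic stack generator
#'
#' Defaults describe the scaled-down desk geometry (256 x 256 x 10 voxels at
#' 140/140/581 nm) with a liver-like field and ZIP foci counts emulating an
#' exposed group: `mu = 5` with `pi0` solved so the true zero fraction is
#' 0.26. `pi0 = 0` recovers a plain Poisson. Noise is Poisson shot noise on
#' expected photons (`intensity / gain`) plus additive Gaussian read noise.
#'
#' @param geometry a [voxel_geometry()]
#' @param n_nuclei named integer vector, nuclei per cell class
#' @param class_params per-class shape parameter list (ranges sampled
#'   uniformly); see `focidose:::default_class_params()` for the fields
#' @param foci_pi0,foci_mu ZIP extra-zero probability and Poisson mean,
#'   either scalars or named per-class vectors
#' @param focus_amplitude,focus_sigma sampling ranges for focus peak
#'   amplitude (counts) and Gaussian width (voxels, isotropic in index space)
#' @param focus_min_sep_vox minimum pairwise centre separation of foci
#'   within a nucleus (voxels): the ground truth represents microscopically
#'   resolvable foci, since merging of sub-resolution focus pairs is an
#'   optical limit, not a property of the counting pipeline
#' @param background named list: `dapi` and `h2ax` field background and
#'   `h2ax_nuclear` diffuse intranuclear gamma-H2AX signal (counts)
#' @param noise named list: `poisson` (logical), `gain` (counts/photon) and
#'   `read_sd` (Gaussian read noise SD, counts); `poisson = FALSE` and
#'   `read_sd = 0` give a noiseless rendering
#' @param margin_px minimum distance from nucleus footprint to image border
#' @param overlap_gap_px minimum clearance between nucleus footprints
#' @param seed integer seed; the scene and rendering are fully determined by it
#' @return an object of class `generator_config`
#' @export
generator_config <- function(geometry = voxel_geometry(nx = 256, ny = 256, nz = 10),
                             n_nuclei = c(hepatocyte = 8, non_hepatocyte = 6),
                             class_params = default_class_params(),
                             foci_pi0 = zip_pi0_for_zero_fraction(0.26, 5),
                             foci_mu = 5,
                             focus_amplitude = c(80, 140),
                             focus_sigma = c(1.2, 1.5),
                             focus_min_sep_vox = 5,
                             background = list(dapi = 2, h2ax = 0.01, h2ax_nuclear = 0.01),
                             noise = list(poisson = TRUE, gain = 1, read_sd = 0.1),
                             margin_px = 3,
                             overlap_gap_px = 3,
                             seed = 1L) {
  stopifnot(all(names(n_nuclei) %in% CELL_CLASSES),
            all(n_nuclei >= 0),
            all(foci_pi0 >= 0), all(foci_pi0 <= 1), all(foci_mu >= 0),
            background$dapi >= 0, background$h2ax >= 0,
            background$h2ax_nuclear >= 0,
            noise$gain > 0, noise$read_sd >= 0)
  structure(list(geometry = geometry, n_nuclei = n_nuclei,
                 class_params = class_params,
                 foci_pi0 = foci_pi0, foci_mu = foci_mu,
                 focus_amplitude = focus_amplitude, focus_sigma = focus_sigma,
                 focus_min_sep_vox = focus_min_sep_vox,
                 background = background, noise = noise,
                 margin_px = margin_px, overlap_gap_px = overlap_gap_px,
                 seed = as.integer(seed)),
            class = "generator_config")
}

class_value <- function(x, cls) {
  if (!is.null(names(x)) && cls %in% names(x)) x[[cls]] else unname(x[[1]])
}

rzip <- function(n, pi0, mu) {
  ifelse(stats::runif(n) < pi0, 0L, stats::rpois(n, mu))
}

runif_range <- function(n, rng) stats::runif(n, rng[1], rng[2])

#' Build a ground-truth scene of nuclei and foci
#'
#' Places the configured number of nuclei per cell class by rejection
#' sampling (footprints pairwise non-overlapping with the configured
#' clearance, fully inside the image margin), then draws per-nucleus focus
#' counts from the configured ZIP law and places foci uniformly within the
#' inner 80% of each nuclear ellipsoid. Fully determined by `config$seed`.
#'
#' @param config a [generator_config()]
#' @return an object of class `clsm_scene`: list with `nuclei` and `foci`
#'   tibbles and the config. Nucleus columns: id, cell_class, cz/cy/cx
#'   (voxels, z/y/x), az/ay/ax (semi-axes, voxels), theta (in-plane
#'   orientation, rad), dapi_amp, n_foci, speckles (list column of per-
#'   speckle dy/dx/dz offsets, sigma, amplitude). Focus columns: id,
#'   nucleus_id, cz/cy/cx (sub-voxel), amplitude, sigma.
#' @export
build_scene <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  g <- config$geometry
  placed <- list()
  nid <- 0L
  for (cls in names(config$n_nuclei)) {
    n <- config$n_nuclei[[cls]]
    if (n == 0) next
    cp <- config$class_params[[cls]]
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        a_major <- runif_range(1, cp$semi_xy)
        ratio <- runif_range(1, cp$axis_ratio)
        a_minor <- a_major / ratio
        az <- runif_range(1, cp$semi_z)
        theta <- stats::runif(1, 0, pi)
        rmax <- a_major
        lo <- config$margin_px + rmax
        cx <- stats::runif(1, lo, g$nx - lo + 1)
        cy <- stats::runif(1, lo, g$ny - lo + 1)
        cz <- g$nz / 2 + 0.5 + stats::runif(1, -1, 1)
        clash <- FALSE
        for (p in placed) {
          dmin <- rmax + p$rmax + config$overlap_gap_px
          if ((cx - p$cx)^2 + (cy - p$cy)^2 < dmin^2) { clash <- TRUE; break }
        }
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place all nuclei without overlap; reduce n_nuclei ",
             "or nucleus size, or enlarge the geometry")
      nid <- nid + 1L
      nsp <- if (cp$n_speckles[2] > 0)
        sample(cp$n_speckles[1]:cp$n_speckles[2], 1) else 0L
      amp <- runif_range(1, cp$dapi_amp)
      speckles <- if (nsp > 0) {
        u <- sample_in_ellipsoid(nsp, az * 0.7, a_minor * 0.7, a_major * 0.7)
        data.frame(dz = u[, 1], dy = u[, 2], dx = u[, 3],
                   sigma = runif_range(nsp, cp$speckle_sigma),
                   amplitude = amp * runif_range(nsp, cp$speckle_amp_frac))
      } else data.frame(dz = numeric(0), dy = numeric(0), dx = numeric(0),
                        sigma = numeric(0), amplitude = numeric(0))
      placed[[nid]] <- list(id = nid, cell_class = cls,
                            cz = cz, cy = cy, cx = cx,
                            az = az, ay = a_minor, ax = a_major,
                            theta = theta, rmax = rmax, dapi_amp = amp,
                            speckles = speckles)
    }
  }
  nuclei <- tibble::tibble(
    id = vapply(placed, `[[`, integer(1), "id"),
    cell_class = vapply(placed, `[[`, character(1), "cell_class"),
    cz = vapply(placed, `[[`, numeric(1), "cz"),
    cy = vapply(placed, `[[`, numeric(1), "cy"),
    cx = vapply(placed, `[[`, numeric(1), "cx"),
    az = vapply(placed, `[[`, numeric(1), "az"),
    ay = vapply(placed, `[[`, numeric(1), "ay"),
    ax = vapply(placed, `[[`, numeric(1), "ax"),
    theta = vapply(placed, `[[`, numeric(1), "theta"),
    dapi_amp = vapply(placed, `[[`, numeric(1), "dapi_amp"),
    speckles = lapply(placed, `[[`, "speckles"))
  # foci
  fl <- list()
  fid <- 0L
  n_foci <- integer(nrow(nuclei))
  for (k in seq_len(nrow(nuclei))) {
    cls <- nuclei$cell_class[k]
    nf <- rzip(1, class_value(config$foci_pi0, cls),
               class_value(config$foci_mu, cls))
    n_foci[k] <- nf
    if (nf == 0) next
    u <- matrix(0, nf, 3)
    for (j in seq_len(nf)) {
      for (try in seq_len(200L)) {
        cand <- sample_in_ellipsoid(1, nuclei$az[k] * 0.8, nuclei$ay[k] * 0.8,
                                    nuclei$ax[k] * 0.8)
        if (j == 1) break
        dmin <- min(sqrt(rowSums(sweep(u[seq_len(j - 1), , drop = FALSE],
                                       2, cand, "-")^2)))
        if (dmin >= config$focus_min_sep_vox) break
      }
      u[j, ] <- cand
    }
    # rotate the ellipse-frame (y', x') offsets into the image frame
    # (inverse of the rotation used in ellipsoid_support)
    th <- nuclei$theta[k]
    dx <- cos(th) * u[, 3] + sin(th) * u[, 2]
    dy <- -sin(th) * u[, 3] + cos(th) * u[, 2]
    for (j in seq_len(nf)) {
      fid <- fid + 1L
      fl[[fid]] <- list(id = fid, nucleus_id = nuclei$id[k],
                        cz = nuclei$cz[k] + u[j, 1],
                        cy = nuclei$cy[k] + dy[j],
                        cx = nuclei$cx[k] + dx[j],
                        amplitude = runif_range(1, config$focus_amplitude),
                        sigma = runif_range(1, config$focus_sigma))
    }
  }
  nuclei$n_foci <- n_foci
  foci <- if (fid > 0) tibble::tibble(
    id = vapply(fl, `[[`, integer(1), "id"),
    nucleus_id = vapply(fl, `[[`, integer(1), "nucleus_id"),
    cz = vapply(fl, `[[`, numeric(1), "cz"),
    cy = vapply(fl, `[[`, numeric(1), "cy"),
    cx = vapply(fl, `[[`, numeric(1), "cx"),
    amplitude = vapply(fl, `[[`, numeric(1), "amplitude"),
    sigma = vapply(fl, `[[`, numeric(1), "sigma"))
  else tibble::tibble(id = integer(0), nucleus_id = integer(0),
                      cz = numeric(0), cy = numeric(0), cx = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0))
  structure(list(nuclei = nuclei, foci = foci, config = config),
            class = "clsm_scene")
}

# uniform samples inside an axis-aligned ellipsoid with semi-axes (az, ay, ax);
# returns a matrix of (dz, dy, dx) offsets
sample_in_ellipsoid <- function(n, az, ay, ax) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- stats::runif(n)^(1 / 3)
  cbind(v[, 1] * r * az, v[, 2] * r * ay, v[, 3] * r * ax)
}

#' Render a scene into a two-channel stack
#'
#' The DAPI channel is field background plus a soft-edged ellipsoid per
#' nucleus (plus heterochromatin speckle Gaussians where the class has
#' them); the gamma-H2AX channel is field background plus a diffuse
#' intranuclear term plus one isotropic (index-space) Gaussian per focus.
#' Shot noise (Poisson on `expected / gain`, scaled back by `gain`) and
#' additive Gaussian read noise follow the config; both can be switched off
#' for a noiseless rendering. Output intensities are non-negative integers.
#'
#' @param scene a [build_scene()] result
#' @param config generator config; defaults to the scene's own
#' @param channels names for the two channels
#' @return a [channel_stack()] with channels `DAPI` and `H2AX`
#' @export
render_stack <- function(scene, config = scene$config,
                         channels = c("DAPI", "H2AX")) {
  stopifnot(inherits(scene, "clsm_scene"))
  g <- config$geometry
  set.seed(config$seed + 1L)
  dims <- c(g$nz, g$ny, g$nx)
  dapi <- array(config$background$dapi, dims)
  h2ax <- array(config$background$h2ax, dims)
  nuc <- scene$nuclei
  for (k in seq_len(nrow(nuc))) {
    sup <- ellipsoid_support(nuc[k, ], dims)
    if (length(sup$idx) == 0) next
    edge <- 0.15  # soft shoulder width in normalized quadratic radius
    w <- pmin(1, pmax(0, (1 - sup$q) / edge))
    dapi[sup$idx] <- dapi[sup$idx] + nuc$dapi_amp[k] * w
    h2ax[sup$idx] <- h2ax[sup$idx] + config$background$h2ax_nuclear * w
    sp <- nuc$speckles[[k]]
    if (nrow(sp) > 0) {
      for (j in seq_len(nrow(sp)))
        dapi <- add_gaussian(dapi, nuc$cz[k] + sp$dz[j], nuc$cy[k] + sp$dy[j],
                             nuc$cx[k] + sp$dx[j], sp$amplitude[j], sp$sigma[j])
    }
  }
  for (j in seq_len(nrow(scene$foci)))
    h2ax <- add_gaussian(h2ax, scene$foci$cz[j], scene$foci$cy[j],
                         scene$foci$cx[j], scene$foci$amplitude[j],
                         scene$foci$sigma[j])
  dapi <- apply_noise(dapi, config$noise)
  h2ax <- apply_noise(h2ax, config$noise)
  out <- list(dapi, h2ax)
  names(out) <- channels
  channel_stack(out, g, metadata = list(synthetic = TRUE, seed = config$seed))
}

# voxels inside (q <= 1) the rotated ellipsoid of one nucleus row; returns
# linear indices and the normalized quadratic radius q at each
ellipsoid_support <- function(nr, dims) {
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  rin <- ceiling(max(nr$ax, nr$ay))
  ylo <- max(1, floor(nr$cy - rin)); yhi <- min(ny, ceiling(nr$cy + rin))
  xlo <- max(1, floor(nr$cx - rin)); xhi <- min(nx, ceiling(nr$cx + rin))
  zlo <- max(1, floor(nr$cz - nr$az - 1)); zhi <- min(nz, ceiling(nr$cz + nr$az + 1))
  zz <- zlo:zhi; yy <- ylo:yhi; xx <- xlo:xhi
  grid <- expand.grid(z = zz, y = yy, x = xx)
  dzv <- grid$z - nr$cz; dyv <- grid$y - nr$cy; dxv <- grid$x - nr$cx
  th <- nr$theta
  # in-plane rotation into the ellipse frame (major axis = x')
  dxp <- dxv * cos(th) - dyv * sin(th)
  dyp <- dxv * sin(th) + dyv * cos(th)
  q <- (dzv / nr$az)^2 + (dyp / nr$ay)^2 + (dxp / nr$ax)^2
  keep <- q <= 1
  idx <- grid$z[keep] + (grid$y[keep] - 1) * nz + (grid$x[keep] - 1) * nz * ny
  list(idx = idx, q = q[keep])
}

add_gaussian <- function(vol, cz, cy, cx, amplitude, sigma) {
  dims <- dim(vol)
  r <- ceiling(4 * sigma)
  zz <- max(1, floor(cz - r)):min(dims[1], ceiling(cz + r))
  yy <- max(1, floor(cy - r)):min(dims[2], ceiling(cy + r))
  xx <- max(1, floor(cx - r)):min(dims[3], ceiling(cx + r))
  gz <- exp(-(zz - cz)^2 / (2 * sigma^2))
  gy <- exp(-(yy - cy)^2 / (2 * sigma^2))
  gx <- exp(-(xx - cx)^2 / (2 * sigma^2))
  blob <- amplitude * outer(outer(gz, gy), gx)
  vol[zz, yy, xx] <- vol[zz, yy, xx] + blob
  vol
}

apply_noise <- function(expected, noise) {
  v <- expected
  if (isTRUE(noise$poisson))
    v <- stats::rpois(length(v), as.vector(v) / noise$gain) * noise$gain
  if (noise$read_sd > 0)
    v <- v + stats::rnorm(length(v), 0, noise$read_sd)
  out <- round(pmax(as.vector(v), 0))
  array(out, dim(expected))
}

#' Export ground truth to CSV
#'
#' Writes `nuclei.csv` (per-nucleus geometry, class, speckle and focus
#' counts) and `foci.csv` (per-focus sub-voxel centre, amplitude, width) into
#' `dir`. Column layout is stable across versions.
#'
#' @param scene a [build_scene()] result
#' @param dir output directory (created if missing)
#' @return named character vector of the two file paths, invisibly
#' @export
export_truth <- function(scene, dir) {
  stopifnot(inherits(scene, "clsm_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nuc <- scene$nuclei
  nuc_out <- data.frame(id = nuc$id, cell_class = nuc$cell_class,
                        cz = nuc$cz, cy = nuc$cy, cx = nuc$cx,
                        az = nuc$az, ay = nuc$ay, ax = nuc$ax,
                        theta = nuc$theta, dapi_amp = nuc$dapi_amp,
                        n_speckles = vapply(nuc$speckles, nrow, integer(1)),
                        n_foci = nuc$n_foci)
  np <- file.path(dir, "nuclei.csv")
  fp <- file.path(dir, "foci.csv")
  utils::write.csv(nuc_out, np, row.names = FALSE)
  utils::write.csv(as.data.frame(scene$foci), fp, row.names = FALSE)
  invisible(c(nuclei = np, foci = fp))
}
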