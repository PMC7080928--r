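#' Voxel geometry of a confocal z-stack
#'
#' Describes the sampling grid of a confocal laser scanning microscopy
#' (CLSM) z-stack. Defaults follow a typical high-magnification acquisition:
#' 1024 x 1024 lateral matrix with 140 nm x/y pixel width and 581 nm z-step
#' over 10 optical sections.
#'
#' @param dx_nm,dy_nm lateral pixel width in nanometres
#' @param dz_nm axial step between optical sections in nanometres
#' @param nx,ny lateral voxel counts
#' @param nz number of optical sections
#' @return an object of class `voxel_geometry`
#' @export
#' @examples
#' voxel_geometry()                 # acquisition defaults
#' voxel_geometry(nx = 256, ny = 256)  # scaled-down desk geometry
voxel_geometry <- function(dx_nm = 140, dy_nm = 140, dz_nm = 581,
                           nx = 1024, ny = 1024, nz = 10) {
  vals <- c(dx_nm = dx_nm, dy_nm = dy_nm, dz_nm = dz_nm,
            nx = nx, ny = ny, nz = nz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all voxel_geometry fields must be strictly positive and finite")
  structure(list(dx_nm = dx_nm, dy_nm = dy_nm, dz_nm = dz_nm,
                 nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz)),
            class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf("voxel_geometry: %d x %d x %d (nx x ny x nz), %g x %g x %g nm\n",
              x$nx, x$ny, x$nz, x$dx_nm, x$dy_nm, x$dz_nm))
  invisible(x)
}

#' Multi-channel 3D intensity stack
#'
#' The unit of image analysis: one non-negative integer intensity volume per
#' named channel (typically `"DAPI"` and `"H2AX"`), plus the voxel geometry
#' and free-form metadata (animal id, group, tissue, acquisition notes).
#' Volumes are stored with axis order `(z, y, x)`, i.e. `dim = c(nz, ny, nx)`.
#'
#' @param channels named list of 3D arrays, each of dim `c(nz, ny, nx)`
#' @param geometry a [voxel_geometry()]
#' @param metadata named list of free-form key/value metadata
#' @return an object of class `channel_stack`
#' @export
channel_stack <- function(channels, geometry, metadata = list()) {
  if (!inherits(geometry, "voxel_geometry")) stop("geometry must be a voxel_geometry")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channels must be uniquely named")
  want <- c(geometry$nz, geometry$ny, geometry$nx)
  for (ch in nm) {
    v <- channels[[ch]]
    if (!is.array(v) || length(dim(v)) != 3 || !all(dim(v) == want))
      stop(sprintf("channel '%s' must have dim (nz, ny, nx) = (%d, %d, %d)",
                   ch, want[1], want[2], want[3]))
    if (min(v) < 0) stop(sprintf("channel '%s' has negative intensities", ch))
  }
  structure(list(channels = channels, geometry = geometry, metadata = metadata),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat("channel_stack with channels:", paste(names(x$channels), collapse = ", "), "\n")
  print(x$geometry)
  if (length(x$metadata))
    cat("metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' 2D intensity image with pixel geometry
#'
#' @param pixels numeric matrix with dim `(ny, nx)`, non-negative
#' @param dx_nm,dy_nm pixel widths in nanometres
#' @return an object of class `image2d` (a matrix with geometry attributes)
#' @export
image2d <- function(pixels, dx_nm = 140, dy_nm = 140) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix (ny, nx)")
  if (min(pixels) < 0) stop("image2d intensities must be non-negative")
  structure(pixels, dx_nm = dx_nm, dy_nm = dy_nm, class = c("image2d", "matrix"))
}

#' Maximum-intensity projection of one channel
#'
#' Projects a channel volume along z: `output[y, x] = max_z volume[z, y, x]`.
#' The 2D projection of the DAPI channel is the input to nucleus mask
#' construction.
#'
#' @param stack a [channel_stack()]
#' @param channel channel name
#' @return an [image2d()] of dim `(ny, nx)`
#' @export
max_intensity_projection <- function(stack, channel) {
  if (!inherits(stack, "channel_stack")) stop("stack must be a channel_stack")
  if (!channel %in% names(stack$channels))
    stop(sprintf("unknown channel '%s'", channel))
  v <- stack$channels[[channel]]
  d <- dim(v)
  m <- v
  dim(m) <- c(d[1], d[2] * d[3])
  out <- do.call(pmax, lapply(seq_len(d[1]), function(z) m[z, ]))
  dim(out) <- c(d[2], d[3])
  image2d(out, dx_nm = stack$geometry$dx_nm, dy_nm = stack$geometry$dy_nm)
}
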