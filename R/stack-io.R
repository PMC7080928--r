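# Multi-page TIFF input/output for channel stacks.
#
# Pages are written channel-interleaved by default (z1/ch1, z1/ch2, z2/ch1,
# ...) or channel-blocked (all z of ch1, then all z of ch2). Intensities are
# stored as unsigned 8- or 16-bit samples; internal computation uses doubles.
# The `tiff` package does not expose the ImageDescription tag, so channel
# names, layout, voxel geometry and metadata are carried in a JSON sidecar
# (`<path>.json`) written next to the TIFF; `read_stack()` uses the sidecar
# when present, then any geometry override, then the documented defaults.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a channel stack to a multi-page TIFF
#'
#' @param stack a [channel_stack()]
#' @param path output TIFF path; a JSON sidecar `<path>.json` is written
#'   alongside with channel names, page layout, geometry and metadata
#' @param layout `"interleaved"` (default) or `"blocked"` page order
#' @param bits_per_sample 8 or 16; intensities must fit the chosen depth
#' @return `path`, invisibly
#' @seealso [read_stack()]
#' @export
write_stack <- function(stack, path, layout = c("interleaved", "blocked"),
                        bits_per_sample = 16L) {
  layout <- match.arg(layout)
  if (!inherits(stack, "channel_stack")) stop("stack must be a channel_stack")
  if (!bits_per_sample %in% c(8L, 16L)) stop("bits_per_sample must be 8 or 16")
  maxval <- 2^bits_per_sample - 1
  for (ch in names(stack$channels)) {
    if (max(stack$channels[[ch]]) > maxval)
      stop(sprintf("channel '%s' exceeds %d-bit range", ch, bits_per_sample))
  }
  g <- stack$geometry
  nms <- names(stack$channels)
  pages <- list()
  if (layout == "interleaved") {
    for (z in seq_len(g$nz)) for (ch in nms)
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][z, , ] / maxval
  } else {
    for (ch in nms) for (z in seq_len(g$nz))
      pages[[length(pages) + 1L]] <- stack$channels[[ch]][z, , ] / maxval
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = bits_per_sample,
                    compression = "none", reduce = FALSE),
    error = function(e) stop(sprintf("cannot write TIFF '%s': %s", path,
                                     conditionMessage(e))))
  meta <- list(channels = nms, layout = layout,
               bits_per_sample = bits_per_sample,
               geometry = unclass(g), metadata = stack$metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a channel stack from a multi-page TIFF
#'
#' The page count must be divisible by the number of channels; `nz` is the
#' quotient. Geometry resolution order: JSON sidecar (written by
#' [write_stack()]) when present, else `geometry_override`, else the
#' acquisition defaults of [voxel_geometry()] (with a warning).
#'
#' @param path TIFF path
#' @param channel_names ordered channel names; defaults to the sidecar's, or
#'   `"ch1"..."chN"` when neither is available (then `n_channels` is needed)
#' @param geometry_override optional [voxel_geometry()] used when no sidecar
#'   geometry is present (lateral/axial spacing; nx/ny/nz are taken from the
#'   file itself)
#' @param layout page layout; defaults to the sidecar's, else `"interleaved"`
#' @param n_channels channel count when `channel_names` is not given
#' @return a [channel_stack()]
#' @export
read_stack <- function(path, channel_names = NULL, geometry_override = NULL,
                       layout = NULL, n_channels = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp))
    meta <- tryCatch(jsonlite::read_json(sp, simplifyVector = TRUE),
                     error = function(e) NULL)
  if (is.null(channel_names)) channel_names <- meta$channels
  if (is.null(channel_names)) {
    if (is.null(n_channels)) n_channels <- 1L
    channel_names <- paste0("ch", seq_len(n_channels))
  }
  if (is.null(layout)) layout <- if (!is.null(meta$layout)) meta$layout else "interleaved"
  layout <- match.arg(layout, c("interleaved", "blocked"))
  nch <- length(channel_names)
  npg <- length(pages)
  if (npg %% nch != 0)
    stop(sprintf("page count (%d) not divisible by channel count (%d)", npg, nch))
  nz <- npg %/% nch
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  bits <- if (!is.null(meta$bits_per_sample)) meta$bits_per_sample else
    attr(pages[[1]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  # as.is=TRUE yields raw integer sample values; rescale only if a reader
  # returned normalized [0,1] doubles
  fractional <- any(vapply(pages, function(p) any(p != floor(p)), logical(1)))
  scale <- if (fractional) 2^bits - 1 else 1
  if (!is.null(meta$geometry)) {
    gm <- meta$geometry
    geom <- voxel_geometry(gm$dx_nm, gm$dy_nm, gm$dz_nm, nx, ny, nz)
  } else if (!is.null(geometry_override)) {
    geom <- voxel_geometry(geometry_override$dx_nm, geometry_override$dy_nm,
                           geometry_override$dz_nm, nx, ny, nz)
  } else {
    warning("no geometry metadata found; falling back to acquisition defaults ",
            "(140/140/581 nm)")
    geom <- voxel_geometry(nx = nx, ny = ny, nz = nz)
  }
  channels <- lapply(channel_names, function(ch) array(0, c(nz, ny, nx)))
  names(channels) <- channel_names
  for (p in seq_len(npg)) {
    if (layout == "interleaved") {
      z <- (p - 1L) %/% nch + 1L
      ci <- (p - 1L) %% nch + 1L
    } else {
      ci <- (p - 1L) %/% nz + 1L
      z <- (p - 1L) %% nz + 1L
    }
    channels[[ci]][z, , ] <- round(pages[[p]] * scale)
  }
  md <- if (!is.null(meta$metadata)) as.list(meta$metadata) else list()
  channel_stack(channels, geom, md)
}
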