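# DAPI-based nucleus segmentation.
#
# Liver protocol: 2D maximum-intensity projection of the DAPI channel ->
# automatic (Otsu) threshold with a multiplicative user adjustment -> binary
# median filter (2-pixel-radius disk) -> distance-transform watershed to
# separate touching nuclei -> fill holes -> area / border filtering -> the
# 2D outlines are extruded unchanged across z to define the 3D regions in
# which gamma-H2AX foci are counted. Testis protocol: user-supplied ROIs
# (see `roi_set()`), no automatic mask.

#' Segmentation parameters
#'
#' @param threshold_method currently `"otsu"`
#' @param threshold_adjust multiplicative user adjustment of the automatic
#'   level (default 1.0, i.e. none)
#' @param median_radius_px radius of the binary median filter disk (default
#'   2, a 13-pixel neighbourhood; 0 disables)
#' @param min_area_px minimum nucleus footprint area in pixels
#' @param border_policy `"exclude"` (default) drops nuclei touching the
#'   image border (partially imaged nuclei bias foci counts); `"keep"` keeps
#'   them
#' @param watershed_enabled apply distance-transform watershed to split
#'   touching nuclei (default TRUE)
#' @param watershed_tolerance minimum depth between distance-map peaks for a
#'   split (pixels); passed to [EBImage::watershed()]
#' @param watershed_ext neighbourhood radius used for peak detection in the
#'   watershed (pixels)
#' @return an object of class `segmentation_params`
#' @export
segmentation_params <- function(threshold_method = "otsu",
                                threshold_adjust = 1.0,
                                median_radius_px = 2,
                                min_area_px = 50,
                                border_policy = c("exclude", "keep"),
                                watershed_enabled = TRUE,
                                watershed_tolerance = 1,
                                watershed_ext = 1) {
  border_policy <- match.arg(border_policy)
  threshold_method <- match.arg(threshold_method, "otsu")
  stopifnot(threshold_adjust > 0, median_radius_px >= 0, min_area_px >= 0)
  structure(list(threshold_method = threshold_method,
                 threshold_adjust = threshold_adjust,
                 median_radius_px = median_radius_px,
                 min_area_px = min_area_px,
                 border_policy = border_policy,
                 watershed_enabled = watershed_enabled,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext),
            class = "segmentation_params")
}

#' Automatic (Otsu) threshold level
#'
#' Exhaustively searches all splits of the observed integer intensity values
#' for the one maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` (Otsu's criterion), and returns the midpoint
#' between the two classes at the optimal split, multiplied by
#' `threshold_adjust`. Foreground is defined as `image > level`.
#'
#' @param image an [image2d()] or plain matrix with at least two distinct
#'   values
#' @param params a [segmentation_params()]
#' @return the threshold level (numeric scalar)
#' @export
auto_threshold <- function(image, params = segmentation_params()) {
  v <- as.vector(image)
  tab <- table(v)
  vals <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  if (length(vals) < 2)
    stop("degenerate histogram: image has fewer than 2 distinct values")
  n <- sum(cnt)
  csum <- cumsum(cnt)
  cmean <- cumsum(cnt * vals)
  total <- cmean[length(cmean)]
  # split after position i: class0 = vals[1..i], class1 = vals[(i+1)..]
  i <- seq_len(length(vals) - 1)
  w0 <- csum[i] / n
  w1 <- 1 - w0
  mu0 <- cmean[i] / csum[i]
  mu1 <- (total - cmean[i]) / (n - csum[i])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  best <- which.max(bcv)
  level <- (vals[best] + vals[best + 1]) / 2
  level * params$threshold_adjust
}

#' Binary median filter over a disk neighbourhood
#'
#' Replaces each pixel by the median of the binary mask over the
#' centre-inclusive Euclidean disk of the given radius (13 pixels at radius
#' 2). At image edges only the in-bounds part of the neighbourhood is used.
#' On binary input the median is the strict majority vote; an exact tie
#' (possible only in even-sized edge neighbourhoods) resolves to background.
#'
#' @param mask logical matrix
#' @param radius_px disk radius in pixels
#' @return filtered logical matrix
#' @export
binary_median_filter <- function(mask, radius_px = 2) {
  if (radius_px == 0) return(mask)
  offs <- disk_offsets(radius_px)
  fg <- matrix(0, nrow(mask), ncol(mask))
  nn <- matrix(0, nrow(mask), ncol(mask))
  m <- mask * 1
  ones <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    fg <- fg + shift_array(m, offs[i, ], 0)
    nn <- nn + shift_array(ones, offs[i, ], 0)
  }
  2 * fg > nn
}

disk_offsets <- function(radius) {
  g <- as.matrix(expand.grid(dy = -radius:radius, dx = -radius:radius))
  g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
}

#' Fill holes in a binary mask
#'
#' Sets to foreground every background component that is not connected to
#' the image border (background connectivity 4, the complement of the
#' 8-connected foreground). Idempotent; never removes foreground.
#'
#' @param mask logical matrix
#' @return filled logical matrix
#' @export
fill_holes <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  # flood the border-connected background
  border <- c(which(bg[1, ]) * d[1] - d[1] + 1,          # row 1
              which(bg[d[1], ]) * d[1],                  # last row
              which(bg[, 1]),                            # col 1
              which(bg[, d[2]]) + (d[2] - 1) * d[1])     # last col
  border <- unique(border[bg[border]])
  if (length(border) == 0) return(matrix(TRUE, d[1], d[2]))  # fully enclosed
  reach <- flood_fill(bg, border, conn_offsets_2d(4))
  out <- matrix(TRUE, d[1], d[2])
  out[reach] <- FALSE
  out
}

#' Per-label region features
#'
#' Area, centroid, perimeter, circularity (`4*pi*area / perimeter^2`),
#' elongation (major/minor axis ratio from image moments), mean DAPI
#' intensity and heterochromatin contrast (0.9-quantile / median intensity
#' within the footprint). Perimeter and moment features come from
#' [EBImage::computeFeatures.shape()] / `computeFeatures.moment()`.
#'
#' @param labels integer label matrix (0 background)
#' @param intensity matching intensity image (the DAPI MIP)
#' @return a tibble with one row per label
#' @export
nucleus_features <- function(labels, intensity) {
  k <- max(labels)
  if (k == 0)
    return(tibble::tibble(label = integer(0), area_px = numeric(0),
                          centroid_y = numeric(0), centroid_x = numeric(0),
                          perimeter_px = numeric(0), circularity = numeric(0),
                          elongation = numeric(0), mean_dapi = numeric(0),
                          hc_contrast = numeric(0)))
  fs <- EBImage::computeFeatures.shape(labels)
  fm <- EBImage::computeFeatures.moment(labels)
  ecc <- fm[, "m.eccentricity"]
  elong <- 1 / sqrt(pmax(1 - ecc^2, 1e-12))
  area <- fs[, "s.area"]
  per <- fs[, "s.perimeter"]
  mean_int <- q90 <- med <- cy <- cx <- numeric(k)
  pix <- which(labels > 0)
  lab_of <- labels[pix]
  for (j in seq_len(k)) {
    pj <- pix[lab_of == j]
    vals <- intensity[pj]
    mean_int[j] <- mean(vals)
    q90[j] <- stats::quantile(vals, 0.9, names = FALSE)
    med[j] <- stats::median(vals)
    rc <- arrayInd(pj, dim(labels))
    cy[j] <- mean(rc[, 1]); cx[j] <- mean(rc[, 2])
  }
  tibble::tibble(label = seq_len(k), area_px = as.numeric(area),
                 centroid_y = cy, centroid_x = cx,
                 perimeter_px = as.numeric(per),
                 circularity = as.numeric(4 * pi * area / per^2),
                 elongation = as.numeric(elong),
                 mean_dapi = mean_int,
                 hc_contrast = q90 / pmax(med, 1e-12))
}

#' Build the nucleus label map from a DAPI projection
#'
#' Pipeline (in order): binarize at [auto_threshold()]; binary median filter
#' over the radius-2 disk; distance-transform watershed to split touching
#' components (when enabled); fill holes; drop regions smaller than
#' `min_area_px`; apply the border policy; relabel consecutively. Features
#' are measured on the final labels.
#'
#' @param mip DAPI maximum-intensity projection ([image2d()] or matrix)
#' @param params a [segmentation_params()]
#' @return an object of class `nucleus_label_map`: list with `labels`
#'   (integer matrix), `features` (tibble, see [nucleus_features()], plus a
#'   `cell_class` column initialized to `NA`), and `params`
#' @export
build_nucleus_label_map <- function(mip, params = segmentation_params()) {
  level <- auto_threshold(mip, params)
  mask <- unclass(mip) > level
  mask <- binary_median_filter(mask, params$median_radius_px)
  if (params$watershed_enabled && any(mask)) {
    dm <- EBImage::distmap(mask * 1)
    labels <- EBImage::imageData(
      EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                         ext = params$watershed_ext))
    storage.mode(labels) <- "integer"
  } else {
    labels <- label_components(mask, conn_offsets_2d(8))
  }
  labels <- fill_label_holes(labels)
  # minimum area
  if (params$min_area_px > 0 && max(labels) > 0) {
    areas <- tabulate(labels[labels > 0], nbins = max(labels))
    drop <- which(areas < params$min_area_px)
    if (length(drop)) labels[labels %in% drop] <- 0L
  }
  if (params$border_policy == "exclude" && max(labels) > 0) {
    d <- dim(labels)
    touching <- unique(c(labels[1, ], labels[d[1], ], labels[, 1], labels[, d[2]]))
    touching <- touching[touching > 0]
    if (length(touching)) labels[labels %in% touching] <- 0L
  }
  labels <- relabel_consecutive(labels)
  if (max(labels) == 0)
    warning("segmentation produced an empty label map")
  feats <- nucleus_features(labels, unclass(mip))
  feats$cell_class <- rep(NA_character_, nrow(feats))
  structure(list(labels = labels, features = feats, params = params),
            class = "nucleus_label_map")
}

# fill holes of the union footprint; each filled pixel inherits the most
# common adjacent label
fill_label_holes <- function(labels) {
  mask <- labels > 0
  filled <- fill_holes(mask)
  holes <- which(filled & !mask)
  if (length(holes) == 0) return(labels)
  hl <- label_components(array(seq_along(labels) %in% holes,
                               dim(labels)), conn_offsets_2d(4))
  for (h in seq_len(max(hl))) {
    hp <- which(hl == h)
    nb <- neighbour_coords(arrayInd(hp, dim(labels)), dim(labels),
                           conn_offsets_2d(8))
    nl <- labels[lin_index(nb$coords, dim(labels))]
    nl <- nl[nl > 0]
    if (length(nl)) labels[hp] <- as.integer(names(which.max(table(nl))))
  }
  labels
}

relabel_consecutive <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  if (length(u) == 0) return(labels)
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  out <- labels
  out[out > 0] <- remap[out[out > 0]]
  out
}

#' Assign cell classes to segmented nuclei
#'
#' Manual rule (the default protocol) copies the provided label -> class
#' mapping verbatim. The auto rule is a morphological convenience: a nucleus
#' is a hepatocyte iff it is round (`circularity >= c_min`), large
#' (`area >= a_min`) and heterochromatin-speckled (`hc_contrast >= h_min`);
#' otherwise a non-hepatocyte iff elongated (`elongation >= e_min`);
#' otherwise unassigned.
#'
#' @param labelmap a [build_nucleus_label_map()] result
#' @param rule `"manual"` (default) or `"auto"`
#' @param manual_labels named vector/list mapping label -> class (manual rule)
#' @param thresholds named list with `c_min`, `a_min`, `h_min`, `e_min`
#' @return the label map with `features$cell_class` filled in
#' @export
classify_nuclei <- function(labelmap, rule = c("manual", "auto"),
                            manual_labels = NULL,
                            thresholds = list(c_min = 0.8, a_min = 500,
                                              h_min = 1.05, e_min = 1.5)) {
  rule <- match.arg(rule)
  f <- labelmap$features
  if (rule == "manual") {
    if (is.null(manual_labels)) stop("manual rule requires manual_labels")
    ids <- as.integer(names(manual_labels))
    if (any(!ids %in% f$label))
      stop("manual_labels references unknown label(s): ",
           paste(setdiff(ids, f$label), collapse = ", "))
    f$cell_class[match(ids, f$label)] <- unlist(manual_labels, use.names = FALSE)
  } else {
    hep <- f$circularity >= thresholds$c_min & f$area_px >= thresholds$a_min &
      f$hc_contrast >= thresholds$h_min
    non <- !hep & f$elongation >= thresholds$e_min
    f$cell_class <- ifelse(hep, "hepatocyte",
                           ifelse(non, "non_hepatocyte", NA_character_))
  }
  labelmap$features <- f
  labelmap
}

#' Extrude a 2D label map across z
#'
#' `volume[z, y, x] = labels[y, x]` for every z: the 2D nuclear outlines are
#' transferred unchanged to the 3D gamma-H2AX stack, defining the regions in
#' which foci are counted.
#'
#' @param labelmap a [build_nucleus_label_map()] result or label matrix
#' @param nz number of optical sections
#' @return integer 3D label array of dim `(nz, ny, nx)`
#' @export
extrude_labels_to_3d <- function(labelmap, nz) {
  stopifnot(nz >= 1)
  labels <- if (inherits(labelmap, "nucleus_label_map")) labelmap$labels else labelmap
  d <- dim(labels)
  out <- array(0L, c(nz, d[1], d[2]))
  for (z in seq_len(nz)) out[z, , ] <- labels
  out
}

#' Manual regions of interest (testis mode)
#'
#' Wraps user-supplied 2D ROIs, given either as a label matrix or as a list
#' of simple polygons (matrices of (y, x) vertices), with the per-ROI
#' nucleus counts needed for foci-per-nucleus normalization.
#'
#' @param rois label matrix or named list of polygon vertex matrices
#' @param dim_yx image dimensions (required for polygons)
#' @param nucleus_counts named numeric vector: nuclei per ROI
#' @return an object of class `roi_set` with a label matrix representation
#' @export
roi_set <- function(rois, dim_yx = NULL, nucleus_counts = NULL) {
  if (is.matrix(rois) && is.numeric(rois)) {
    labels <- rois
    storage.mode(labels) <- "integer"
  } else if (is.list(rois)) {
    if (is.null(dim_yx)) stop("dim_yx required for polygon ROIs")
    labels <- matrix(0L, dim_yx[1], dim_yx[2])
    for (i in seq_along(rois)) {
      poly <- rois[[i]]
      if (any(poly[, 1] < 1 | poly[, 1] > dim_yx[1] |
              poly[, 2] < 1 | poly[, 2] > dim_yx[2]))
        stop("ROI polygon outside image bounds")
      inside <- points_in_polygon(dim_yx, poly)
      labels[inside] <- i
    }
  } else stop("rois must be a label matrix or list of polygons")
  structure(list(labels = labels, nucleus_counts = nucleus_counts),
            class = "roi_set")
}

# even-odd rule point-in-polygon over the full pixel grid
points_in_polygon <- function(dim_yx, poly) {
  yy <- rep(seq_len(dim_yx[1]), times = dim_yx[2])
  xx <- rep(seq_len(dim_yx[2]), each = dim_yx[1])
  n <- nrow(poly)
  inside <- rep(FALSE, length(yy))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > yy) != (yj > yy)) &
      (xx < (xj - xi) * (yy - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  which(inside)
}
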