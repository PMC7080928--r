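#' Liver-protocol analysis of one two-channel stack
#'
#' Runs the full liver pipeline on a stack: DAPI maximum-intensity
#' projection, nucleus label map, extrusion across z, foci detection in the
#' gamma-H2AX channel restricted to the nuclear regions, and per-nucleus
#' counts (zero-count nuclei included). Optionally classifies nuclei.
#'
#' @param stack a [channel_stack()] with DAPI and gamma-H2AX channels
#' @param dapi,h2ax channel names
#' @param seg_params a [segmentation_params()]
#' @param foci_params_ a [foci_params()] (liver default `min_voxels = 8`)
#' @param classify `"none"`, `"auto"`, or `"manual"`
#' @param manual_labels label -> class mapping when `classify = "manual"`
#' @return list: `labelmap` ([build_nucleus_label_map()] result),
#'   `fociset`, `counts` (tibble: nucleus_id, n_foci, cell_class)
#' @export
analyze_liver_stack <- function(stack, dapi = "DAPI", h2ax = "H2AX",
                                seg_params = segmentation_params(),
                                foci_params_ = foci_params(min_voxels = 8L),
                                classify = c("none", "auto", "manual"),
                                manual_labels = NULL) {
  classify <- match.arg(classify)
  mip <- max_intensity_projection(stack, dapi)
  lm <- build_nucleus_label_map(mip, seg_params)
  if (classify != "none")
    lm <- classify_nuclei(lm, rule = classify, manual_labels = manual_labels)
  vol3 <- extrude_labels_to_3d(lm, stack$geometry$nz)
  fs <- detect_foci(stack$channels[[h2ax]], foci_params_, mask = vol3,
                    mode = "per_nucleus")
  res <- assign_foci_to_nuclei(fs, vol3)
  counts <- res$counts
  counts$cell_class <- lm$features$cell_class[match(counts$nucleus_id,
                                                    lm$features$label)]
  list(labelmap = lm, fociset = res$fociset, counts = counts)
}
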