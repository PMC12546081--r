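#' Estimate the background noise level of a volume
#'
#' Standard deviation of intensities inside a vessel-free background region.
#' Feeds the "five times background noise" magnitude threshold of the
#' phase-contrast pipeline and SNR bookkeeping for the TOF phantoms. If the
#' region overlaps vessel signal the estimate is biased high; that is a
#' documented property, not an error.
#'
#' @param volume a [voxel_grid()] (or array).
#' @param background_region logical/binary array of the same shape selecting
#'   background voxels.
#' @return noise SD in intensity units.
#' @export
estimate_noise <- function(volume, background_region) {
  vals <- if (inherits(volume, "voxel_grid")) volume$values else volume
  sel <- background_region != 0
  if (!identical(dim(vals), dim(sel)))
    stop_input("background_region shape does not match the volume")
  if (!any(sel)) stop_input("background_region is empty")
  stats::sd(vals[sel])
}

#' Threshold-based vessel segmentation with 18-connectivity labeling
#'
#' Voxels at or above the intensity threshold form the foreground; connected
#' components are labeled treating voxels as connected when their faces or
#' edges are adjacent (18-neighborhood; corner-only contact does not
#' connect). An empty foreground yields a valid mask flagged `empty`, not an
#' error.
#'
#' @param volume a [voxel_grid()].
#' @param threshold finite intensity threshold.
#' @param connectivity 6, 18 (default) or 26.
#' @return object of class `vessel_mask`: `mask` (logical array),
#'   `component_labels` (integer array, 0 = background), `n_components`,
#'   `empty`, and the source grid geometry.
#' @export
threshold_segment <- function(volume, threshold, connectivity = 18L) {
  if (!inherits(volume, "voxel_grid")) volume <- voxel_grid(volume, 1)
  if (!is.finite(threshold)) stop_input("threshold must be finite")
  m <- volume$values >= threshold
  labels <- .cpp_label_components(as.integer(m), dim(m),
                                  as.integer(connectivity))
  structure(list(mask = m, component_labels = labels,
                 n_components = max(labels), empty = !any(m),
                 spacing_mm = volume$spacing_mm,
                 origin_mm = volume$origin_mm),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %s, %d component(s), %d foreground voxel(s)\n",
              paste(dim(x$mask), collapse = "x"), x$n_components,
              sum(x$mask)))
  invisible(x)
}

#' Keep only the component containing a seed voxel
#'
#' Implements the ROI step of the vessel workflow: the user (or phantom
#' truth) points at the artery of interest and everything else is dropped.
#'
#' @param mask a `vessel_mask` from [threshold_segment()].
#' @param seed_point length-3 integer voxel index (1-based).
#' @return a single-component `vessel_mask`.
#' @export
select_component <- function(mask, seed_point) {
  if (!inherits(mask, "vessel_mask")) stop_input("mask must be a vessel_mask")
  seed_point <- as.integer(round(seed_point))
  d <- dim(mask$mask)
  if (any(seed_point < 1L) || any(seed_point > d))
    stop_input("seed_point is outside the volume")
  lab <- mask$component_labels[seed_point[1], seed_point[2], seed_point[3]]
  if (lab == 0L) stop_input("seed_point lies in the background")
  keep <- mask$component_labels == lab
  labels <- array(0L, d)
  labels[keep] <- 1L
  structure(list(mask = keep, component_labels = labels, n_components = 1L,
                 empty = FALSE, spacing_mm = mask$spacing_mm,
                 origin_mm = mask$origin_mm),
            class = "vessel_mask")
}
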