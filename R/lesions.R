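#' Generate a lesion/ventricle scene with known distances
#'
#' The ventricle is modeled as an axis-aligned slab filling the bottom
#' `ventricle_slices` of the volume, so the distance from any voxel above
#' it to the ventricle is a closed-form vertical distance and the 13-mm
#' periventricular/deep rule is analytically checkable. Each requested
#' lesion is a small box placed so that the centre of its lowest voxel
#' layer sits at the requested vertical offset from the centre of the top
#' ventricle layer; offsets are realized exactly when they are multiples of
#' the z spacing and to the nearest voxel otherwise (always within half a
#' voxel). Ground-truth distances and labels refer to the realized
#' positions.
#'
#' @param component_offsets_mm vector of requested minimum distances (mm)
#'   from the ventricular surface, each >= one z spacing (a smaller offset
#'   would overlap the ventricle).
#' @param component_size_vox lesion box edge length in voxels (scalar or
#'   per-component; default 3).
#' @param spacing_mm voxel spacing (scalar or length 3).
#' @param ventricle_slices slab thickness in voxels (default 5).
#' @param pv_dwm_threshold_mm classification threshold (default 13).
#' @return object of class `lesion_scene`: `lesion_mask`, `ventricle_mask`
#'   ([voxel_grid()]s), `truth` data frame (`component_id`,
#'   `requested_offset_mm`, `truth_min_distance_mm`, `truth_label`).
#' @export
gen_lesion_scene <- function(component_offsets_mm, component_size_vox = 3L,
                             spacing_mm = 1, ventricle_slices = 5L,
                             pv_dwm_threshold_mm = 13) {
  spacing_mm <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3L)
                else as.numeric(spacing_mm)
  m <- length(component_offsets_mm)
  sizes <- rep_len(as.integer(component_size_vox), max(m, 1L))
  if (m && any(component_offsets_mm < spacing_mm[3] - 1e-9))
    stop_input("offsets below one z spacing would overlap the ventricle")
  dz <- spacing_mm[3]
  zoff <- if (m) as.integer(round(component_offsets_mm / dz)) else integer(0)
  realized <- zoff * dz

  gap <- 3L
  nx <- max(8L, sum(sizes + gap) + gap)
  ny <- max(8L, max(sizes, 0L) + 2L * gap)
  nz <- ventricle_slices +
    (if (m) max(zoff + sizes) else 0L) + gap
  d <- c(nx, ny, nz)
  vent <- array(FALSE, d)
  vent[, , seq_len(ventricle_slices)] <- TRUE
  les <- array(FALSE, d)
  x0 <- gap + 1L
  placed <- integer(m)
  for (i in seq_len(m)) {
    s <- sizes[i]
    zlo <- ventricle_slices + zoff[i] # 1-based index of lowest lesion layer
    les[x0:(x0 + s - 1L), (gap + 1L):(gap + s), zlo:(zlo + s - 1L)] <- TRUE
    placed[i] <- x0
    x0 <- x0 + s + gap
  }
  if (any(les & vent)) stop_input("lesion components overlap the ventricle")

  # components are id-ordered by first voxel in scan order (z-major last),
  # i.e. by realized offset, then x; map truth rows to that ordering
  ord <- order(zoff, placed)
  truth <- data.frame(
    component_id = seq_len(m),
    requested_offset_mm = component_offsets_mm[ord],
    truth_min_distance_mm = realized[ord],
    truth_label = ifelse(realized[ord] >= pv_dwm_threshold_mm, "DWM", "PVWM"),
    stringsAsFactors = FALSE)

  structure(list(
    lesion_mask = voxel_grid(les * 1, spacing_mm),
    ventricle_mask = voxel_grid(vent * 1, spacing_mm),
    truth = truth, pv_dwm_threshold_mm = pv_dwm_threshold_mm),
    class = "lesion_scene")
}

#' Connected lesion components
#'
#' Labels an ingested binary lesion mask into 18-connectivity components
#' with deterministic ids (scan order of the first voxel). Optionally a
#' probability map can be supplied instead of a binary mask, in which case
#' it is binarized at `prob_threshold` first (the convention of ensemble
#' U-Net lesion segmenters, whose default cut is 0.5).
#'
#' @param lesion_mask binary [voxel_grid()]/array, or a probability map.
#' @param prob_threshold threshold applied when values are not 0/1
#'   (default 0.5).
#' @param connectivity 6, 18 (default) or 26.
#' @return object of class `lesion_components`: `table` data frame
#'   (`component_id`, `voxel_count`), `voxel_idx` (list of linear indices),
#'   `dim`, `spacing_mm`.
#' @export
lesion_components <- function(lesion_mask, prob_threshold = 0.5,
                              connectivity = 18L) {
  if (inherits(lesion_mask, "voxel_grid")) {
    vals <- lesion_mask$values
    sp <- lesion_mask$spacing_mm
  } else {
    vals <- lesion_mask
    sp <- c(1, 1, 1)
  }
  binary <- all(vals %in% c(0, 1))
  m <- if (binary) vals != 0 else vals >= prob_threshold
  labels <- .cpp_label_components(as.integer(m), dim(m),
                                  as.integer(connectivity))
  k <- max(labels)
  idx <- if (k) split(which(labels != 0), labels[labels != 0]) else list()
  structure(list(
    table = data.frame(component_id = seq_len(k),
                       voxel_count = vapply(idx, length, integer(1),
                                            USE.NAMES = FALSE)),
    voxel_idx = unname(idx), dim = dim(m), spacing_mm = sp),
    class = "lesion_components")
}

#' Minimum distance from each lesion component to the ventricle
#'
#' Euclidean distance transform of the ventricle (0 inside, anisotropic
#' spacing honored), sampled at the lesion voxels; the per-component
#' minimum is the component's distance to the ventricular surface.
#'
#' @param components a `lesion_components` object.
#' @param ventricle_mask binary [voxel_grid()]/array aligned with the
#'   lesion mask; must be non-empty.
#' @return `components` with a `min_distance_mm` column added.
#' @export
distance_to_ventricle <- function(components, ventricle_mask) {
  vm <- if (inherits(ventricle_mask, "voxel_grid")) ventricle_mask
        else voxel_grid(ventricle_mask, components$spacing_mm)
  if (!identical(dim(vm$values), components$dim))
    stop_input("ventricle mask shape does not match the lesion mask")
  if (!any(vm$values != 0)) stop_input("ventricle mask is empty")
  dmap <- distance_transform(vm)$values
  components$table$min_distance_mm <-
    vapply(components$voxel_idx, function(ii) min(dmap[ii]), numeric(1))
  components
}

#' Classify lesion components as periventricular or deep white matter
#'
#' A component is deep white matter (DWM) when its minimum distance to the
#' ventricular surface is 13 mm or more ("13 mm or further"); otherwise it
#' is periventricular (PVWM). Classification is per component: a lesion
#' straddling the boundary is periventricular because part of it lies
#' nearer. Set `per_voxel = TRUE` to instead split each component's voxels
#' across the two classes by their individual distances.
#'
#' @param components a `lesion_components` object with distances computed
#'   by [distance_to_ventricle()].
#' @param threshold_mm rule threshold (default 13).
#' @param per_voxel voxel-wise classification variant (default FALSE).
#' @param ventricle_mask required when `per_voxel = TRUE`.
#' @return `components` with a `label` column (and, per voxel,
#'   `pvwm_voxels`/`dwm_voxels` counts).
#' @export
classify_pv_dwm <- function(components, threshold_mm = 13,
                            per_voxel = FALSE, ventricle_mask = NULL) {
  if (is.null(components$table$min_distance_mm))
    stop_input("run distance_to_ventricle() first")
  components$table$label <-
    ifelse(components$table$min_distance_mm >= threshold_mm, "DWM", "PVWM")
  if (per_voxel) {
    if (is.null(ventricle_mask))
      stop_input("per-voxel classification needs the ventricle mask")
    vm <- if (inherits(ventricle_mask, "voxel_grid")) ventricle_mask
          else voxel_grid(ventricle_mask, components$spacing_mm)
    dmap <- distance_transform(vm)$values
    components$table$dwm_voxels <- vapply(
      components$voxel_idx, function(ii) sum(dmap[ii] >= threshold_mm),
      integer(1))
    components$table$pvwm_voxels <-
      components$table$voxel_count - components$table$dwm_voxels
  }
  components
}

#' Lesion volumes per class
#'
#' Volume = number of voxels x voxel volume. Totals are additive: the
#' periventricular and deep volumes always sum exactly to the total.
#'
#' @param components a classified `lesion_components` object.
#' @param voxel_volume_mm3 voxel volume in mm^3; default from the
#'   component spacing.
#' @return list with `total_cm3`, `pvwm_cm3`, `dwm_cm3`, `n_components`.
#' @export
lesion_volumes <- function(components, voxel_volume_mm3 = NULL) {
  if (is.null(voxel_volume_mm3))
    voxel_volume_mm3 <- prod(components$spacing_mm)
  if (voxel_volume_mm3 <= 0) stop_input("voxel_volume_mm3 must be positive")
  tab <- components$table
  vol <- function(nvox) nvox * voxel_volume_mm3 / 1000
  if (!nrow(tab))
    return(list(total_cm3 = 0, pvwm_cm3 = 0, dwm_cm3 = 0, n_components = 0L))
  if (is.null(tab$label))
    stop_input("run classify_pv_dwm() first")
  pv <- sum(tab$voxel_count[tab$label == "PVWM"])
  dw <- sum(tab$voxel_count[tab$label == "DWM"])
  list(total_cm3 = vol(pv + dw), pvwm_cm3 = vol(pv), dwm_cm3 = vol(dw),
       n_components = nrow(tab))
}
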