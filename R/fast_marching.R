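#' Fast-marching arrival times on a masked volume
#'
#' Solves the Eikonal equation `|grad T| = 1/F` for the first-arrival time
#' of a front expanding from a source voxel at spatially varying speed `F`,
#' using an upwind fast-marching scheme with second-order one-sided
#' stencils (first-order fallback where a second accepted neighbour is not
#' available) on the anisotropic voxel lattice. Voxels with non-positive or
#' undefined speed are outside the domain and keep `T = Inf`. A small ball
#' around the source is initialized with the exact local solution to remove
#' the large first-order error of the immediate neighbours.
#'
#' @param speed a [voxel_grid()] (or array) of front speeds; `> 0` inside
#'   the domain, `<= 0`/`NA` outside.
#' @param source_voxel length-3 integer voxel index (1-based) inside the
#'   domain.
#' @param order stencil order, 1 or 2 (default 2).
#' @param init_radius_vox radius (in voxels of the largest spacing) of the
#'   exactly initialized source ball; default 4.
#' @return a [voxel_grid()] of arrival times (`Inf` where unreachable),
#'   with attribute `source_voxel`.
#' @export
msfm_arrival <- function(speed, source_voxel, order = 2L,
                         init_radius_vox = 4) {
  if (!inherits(speed, "voxel_grid")) speed <- voxel_grid(speed, 1)
  f <- speed$values
  if (all(!is.finite(f) | f <= 0)) stop_input("speed has no positive voxels")
  if (any(f[is.finite(f)] < 0)) stop_input("speed must be positive inside the domain")
  src <- as.integer(round(source_voxel))
  d <- dim(f)
  if (length(src) != 3L || any(src < 1L) || any(src > d))
    stop_input("source_voxel is outside the volume")
  if (!is.finite(f[src[1], src[2], src[3]]) || f[src[1], src[2], src[3]] <= 0)
    stop_input("source_voxel lies outside the speed domain")
  T <- .cpp_fmm_arrival(as.numeric(f), d, speed$spacing_mm, src - 1L,
                        as.integer(order), init_radius_vox)
  out <- voxel_grid(array(T, d), speed$spacing_mm, speed$origin_mm)
  attr(out, "source_voxel") <- src
  out
}

#' Sub-voxel geodesic backtracking on an arrival-time field
#'
#' Descends the arrival-time field from an end voxel to the source by
#' gradient descent with trilinear interpolation of the per-voxel gradient,
#' step `0.4 x` the smallest voxel spacing. When interpolation stalls (flat
#' or conflicting gradients near the mask boundary) the walker falls back
#' to the steepest discrete neighbour. The result is an ordered mm-space
#' polyline from the end point down to the source.
#'
#' @param arrival_field output of [msfm_arrival()].
#' @param end_point length-3 voxel index (1-based) with finite arrival time.
#' @param step_factor descent step as a fraction of min spacing
#'   (default 0.4).
#' @return a [centerline()] ordered source -> end point.
#' @export
backtrack_path <- function(arrival_field, end_point, step_factor = 0.4) {
  Tg <- arrival_field
  Tv <- Tg$values
  d <- dim(Tv)
  src <- attr(arrival_field, "source_voxel")
  if (is.null(src)) stop_input("arrival_field lacks a source_voxel attribute")
  ep <- as.integer(round(end_point))
  if (any(ep < 1L) || any(ep > d) || !is.finite(Tv[ep[1], ep[2], ep[3]]))
    stop_input("end_point has no finite arrival time")
  h <- Tg$spacing_mm
  if (all(ep == src))
    return(centerline(index_to_physical(Tg, matrix(src, 1))))

  # cap unreachable voxels so boundary gradients point inward
  finiteT <- is.finite(Tv)
  cap <- max(Tv[finiteT]) + max(h)
  Tc <- Tv
  Tc[!finiteT] <- cap

  grad <- vapply(1:3, function(a) {
    prv <- shift_array(Tc, a, -1L, cap) # value at index - 1
    nxt <- shift_array(Tc, a, +1L, cap) # value at index + 1
    (nxt - prv) / (2 * h[a])
  }, Tc)
  dim(grad) <- c(d, 3L)

  src_xyz <- index_to_physical(Tg, matrix(src, 1))[1, ]
  pos <- index_to_physical(Tg, matrix(ep, 1))[1, ]
  step <- step_factor * min(h)
  max_steps <- ceiling(4 * sum(d * h) / step) + 1000L
  pts <- matrix(NA_real_, max_steps, 3L)
  n <- 1L
  pts[1, ] <- pos
  t_prev <- interp3(Tc, Tg, pos)

  for (it in seq_len(max_steps - 1L)) {
    if (sqrt(sum((pos - src_xyz)^2)) <= max(h)) break
    g <- c(interp3(grad[, , , 1], Tg, pos), interp3(grad[, , , 2], Tg, pos),
           interp3(grad[, , , 3], Tg, pos))
    gn <- sqrt(sum(g^2))
    moved <- FALSE
    if (is.finite(gn) && gn > 1e-12) {
      cand <- pos - step * g / gn
      t_new <- interp3(Tc, Tg, cand)
      if (is.finite(t_new) && t_new < t_prev - 1e-12) {
        pos <- cand; t_prev <- t_new; moved <- TRUE
      }
    }
    if (!moved) {
      # steepest discrete neighbour fallback
      vox <- pmin(pmax(round(physical_to_index(Tg, matrix(pos, 1))[1, ]), 1), d)
      best <- NULL; bestT <- Tc[vox[1], vox[2], vox[3]]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        v <- vox + c(dx, dy, dz)
        if (any(v < 1L) || any(v > d)) next
        tv <- Tv[v[1], v[2], v[3]]
        if (is.finite(tv) && tv < bestT) { bestT <- tv; best <- v }
      }
      if (is.null(best))
        stop_input("backtracking stalled on a plateau at voxel (%d, %d, %d)",
                   vox[1], vox[2], vox[3])
      pos <- index_to_physical(Tg, matrix(best, 1))[1, ]
      t_prev <- bestT
    }
    n <- n + 1L
    pts[n, ] <- pos
  }
  n <- n + 1L
  pts[n, ] <- src_xyz
  centerline(pts[n:1, , drop = FALSE])
}

shift_array <- function(a, axis, by, fill) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[axis]] <- pmin(pmax(idx[[axis]] + by, 1L), d[axis])
  out <- do.call(`[`, c(list(a), src))
  dim(out) <- d
  # voxels whose shifted source was clamped keep their own (edge) value;
  # this yields one-sided differences at the boundary
  out
}

interp3 <- function(a, g, xyz) {
  fi <- physical_to_index(g, matrix(xyz, 1))[1, ]
  d <- dim(a)
  fi <- pmin(pmax(fi, 1), d)
  i0 <- pmin(floor(fi), d - 1L); i0 <- pmax(i0, 1L)
  fr <- fi - i0
  acc <- 0
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    w <- (if (cx) fr[1] else 1 - fr[1]) *
         (if (cy) fr[2] else 1 - fr[2]) *
         (if (cz) fr[3] else 1 - fr[3])
    if (w > 0) acc <- acc + w * a[i0[1] + cx, i0[2] + cy, i0[3] + cz]
  }
  acc
}

#' Extract a vessel centerline from a single-component mask
#'
#' The fast-marching speed is a medialness prior: the interior distance
#' transform of the mask raised to `medialness_power` and normalized to a
#' maximum of 1, so the front runs fastest along the vessel axis and
#' minimal-time geodesics are pulled onto it. The far endpoint is the voxel
#' of maximal arrival time; the geodesic from it back to the source is the
#' centerline, resampled at `step_mm`.
#'
#' @param mask a single-component `vessel_mask` (or logical array).
#' @param source length-3 voxel index (1-based) inside the mask, typically
#'   one anatomical end of the vessel.
#' @param step_mm resampling step (default half the smallest spacing).
#' @param medialness_power exponent on the normalized interior distance
#'   (default 2).
#' @param spacing_mm used when `mask` is a plain array.
#' @return a [centerline()] from the source to the far endpoint.
#' @export
extract_centerline <- function(mask, source, step_mm = NULL,
                               medialness_power = 2, spacing_mm = 1) {
  if (inherits(mask, "vessel_mask")) {
    m <- mask$mask; sp <- mask$spacing_mm; orig <- mask$origin_mm
  } else {
    m <- mask != 0
    sp <- if (length(spacing_mm) == 1L) rep(spacing_mm, 3L) else spacing_mm
    orig <- c(0, 0, 0)
  }
  if (!any(m)) stop_input("mask is empty")
  mg <- voxel_grid(m * 1, sp, orig)
  depth <- distance_transform(mg, invert = TRUE)$values
  depth[!m] <- 0
  dmax <- max(depth)
  if (dmax <= 0) stop_input("mask is degenerate (no interior)")
  speed <- (depth / dmax)^medialness_power
  speed[!m] <- 0
  Tg <- msfm_arrival(voxel_grid(speed, sp, orig), source)
  Tv <- Tg$values
  Tv[!is.finite(Tv)] <- -Inf
  # endpoint: raw argmax T tends to sit in slow near-wall corners rather
  # than at the anatomical far end of the lumen, so restrict to reasonably
  # interior voxels, take the latest-arrival band, and pick its most
  # medial (deepest) voxel
  medial <- depth >= 0.6 * dmax & is.finite(Tg$values)
  if (any(medial)) {
    tmax <- max(Tv[medial])
    band <- medial & Tv >= tmax - 3 * max(sp)
    cand <- which(band)
    far <- arrayInd(cand[which.max(depth[cand])], dim(Tv))[1, ]
  } else {
    far <- arrayInd(which.max(Tv), dim(Tv))[1, ]
  }
  cl <- backtrack_path(Tg, far)
  if (is.null(step_mm)) step_mm <- min(sp) / 2
  # light Gaussian smoothing (sigma = half a voxel of arc length) removes
  # sub-voxel descent jitter that would otherwise inflate the path length;
  # heavier smoothing starts shrinking genuine curvature
  fine_step <- 0.4 * min(sp)
  fine <- resample_centerline(cl, fine_step)
  if (nrow(fine$points) >= 5L) {
    sm <- apply(fine$points, 2L, gauss_smooth,
                sigma = 0.5 * min(sp) / fine_step)
    fine <- centerline(sm)
  }
  resample_centerline(fine, step_mm)
}
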