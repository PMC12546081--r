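#' Ordered physical-coordinate polyline with arc length
#'
#' The substrate of all tortuosity computations: an ordered sequence of
#' points in physical (mm) coordinates with the cumulative arc length along
#' the polyline. `L_path` is the total arc length, `L_chord` the straight
#' distance between the endpoints.
#'
#' @param points n x 3 numeric matrix of mm coordinates (n >= 1).
#' @return object of class `centerline` with `points` and
#'   `cum_arc_length_mm`.
#' @export
centerline <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  if (nrow(points) < 1L || any(!is.finite(points)))
    stop_input("centerline needs at least one finite point")
  seg <- if (nrow(points) > 1L) sqrt(rowSums(diff(points)^2)) else numeric(0)
  structure(list(points = points, cum_arc_length_mm = c(0, cumsum(seg))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, L_path = %.3f mm, L_chord = %.3f mm\n",
              nrow(x$points), path_length(x), chord_length(x)))
  invisible(x)
}

#' Path (arc) length of a centerline in mm
#' @param cl a [centerline()].
#' @export
path_length <- function(cl) {
  cl$cum_arc_length_mm[length(cl$cum_arc_length_mm)]
}

#' Chord (endpoint-to-endpoint) length of a centerline in mm
#' @param cl a [centerline()].
#' @export
chord_length <- function(cl) {
  n <- nrow(cl$points)
  sqrt(sum((cl$points[n, ] - cl$points[1, ])^2))
}

#' Resample a centerline at a uniform arc-length step
#'
#' Points are placed at exact multiples of `step_mm` along the polyline;
#' the original final point is appended when it lies more than 1e-6 mm
#' beyond the last full step, so the endpoints (and hence the chord) are
#' preserved while interior spacing equals the requested step.
#'
#' @param cl a [centerline()].
#' @param step_mm positive resampling step, mm.
#' @return a resampled [centerline()].
#' @export
resample_centerline <- function(cl, step_mm) {
  if (step_mm <= 0) stop_input("step_mm must be positive")
  L <- path_length(cl)
  if (L == 0) return(cl)
  s_tgt <- seq(0, L, by = step_mm)
  if (L - s_tgt[length(s_tgt)] > 1e-6) s_tgt <- c(s_tgt, L)
  s <- cl$cum_arc_length_mm
  # guard against zero-length segments for approx()
  keep <- c(TRUE, diff(s) > 0)
  s <- s[keep]; pts <- cl$points[keep, , drop = FALSE]
  out <- vapply(1:3, function(a)
    stats::approx(s, pts[, a], xout = s_tgt, ties = "ordered")$y,
    numeric(length(s_tgt)))
  centerline(out)
}
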