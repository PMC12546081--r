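#' Count vessel turns by Frenet-normal reversal
#'
#' Automates the inflection count on a centerline: after Gaussian smoothing
#' of the coordinates, the discrete Frenet normal (the component of the
#' second arc-length derivative perpendicular to the tangent) is tracked
#' along the curve, and a turn is recorded wherever consecutive unit
#' normals reverse (dot product < 0). Nearly straight stretches
#' (curvature < `kappa_min`) carry no orientation information and are
#' skipped; orientation lobes shorter than `min_separation_mm` of arc are
#' treated as noise and removed parity-consistently before counting.
#'
#' A straight line and a constant-curvature arc (e.g. a semicircle or a
#' helix) have zero turns; a planar sinusoid with `k` periods has `2k - 1`.
#'
#' @param cl a [centerline()] resampled at a uniform step (>= 5 points).
#' @param kappa_min absolute curvature floor in 1/mm below which the
#'   normal is considered undefined (default 1e-3).
#' @param kappa_rel relative confidence threshold: samples additionally
#'   need curvature >= `kappa_rel` times the robust (95th percentile)
#'   curvature of the trimmed curve, which keeps residual discretization
#'   wiggle from carrying orientation on gently curved vessels
#'   (default 0.25).
#' @param smooth_sigma_mm SD of the Gaussian coordinate smoothing in mm;
#'   default four times the resampling step.
#' @param min_separation_mm minimum arc length an orientation must
#'   persist to count as a genuine lobe between turns; shorter lobes are
#'   treated as noise and annihilated parity-consistently (default 5 mm).
#' @param trim_mm arc length ignored at each end of the curve, where
#'   discrete tangents are unreliable (default 4 mm).
#' @return non-negative integer turn count.
#' @export
count_turns <- function(cl, kappa_min = 1e-3, kappa_rel = 0.25,
                        smooth_sigma_mm = NULL,
                        min_separation_mm = 5, trim_mm = 4) {
  if (!inherits(cl, "centerline")) stop_input("cl must be a centerline")
  n <- nrow(cl$points)
  if (n < 5L) stop_input("centerline must have at least 5 points")
  steps <- diff(cl$cum_arc_length_mm)
  step <- stats::median(steps)
  if (step <= 0) stop_input("centerline is degenerate (zero step)")
  if (is.null(smooth_sigma_mm)) smooth_sigma_mm <- 4 * step

  p <- apply(cl$points, 2L, gauss_smooth, sigma = smooth_sigma_mm / step)
  s <- cl$cum_arc_length_mm

  idx <- 2:(n - 1L)
  d1 <- (p[idx + 1L, , drop = FALSE] - p[idx - 1L, , drop = FALSE]) /
        (2 * step)
  d2 <- (p[idx + 1L, , drop = FALSE] - 2 * p[idx, , drop = FALSE] +
         p[idx - 1L, , drop = FALSE]) / step^2
  sp2 <- rowSums(d1^2)
  tn <- d1 / sqrt(sp2)
  proj <- rowSums(d2 * tn)
  nrm <- d2 - proj * tn
  kappa <- sqrt(rowSums(nrm^2)) / sp2

  span <- s[idx] >= trim_mm & s[idx] <= s[n] - trim_mm
  if (!any(span)) return(0L)
  kappa_hi <- max(kappa_min, kappa_rel * stats::quantile(kappa[span], 0.95))
  valid <- kappa >= kappa_hi & span
  if (sum(valid) < 2L) return(0L)
  vi <- which(valid)
  un <- nrm[vi, , drop = FALSE] / sqrt(rowSums(nrm[vi, , drop = FALSE]^2))
  dots <- rowSums(un[-1L, , drop = FALSE] * un[-nrow(un), , drop = FALSE])
  flips <- which(dots < 0)
  if (!length(flips)) return(0L)
  flip_s <- s[idx[vi[flips]]]
  lo <- s[idx[vi[1]]]
  hi <- s[idx[vi[length(vi)]]]
  # parity-aware cleanup: an orientation lobe shorter than the persistence
  # window is noise -- an interior short lobe annihilates its two bounding
  # reversals (flip + flip-back), a short edge lobe drops its single one
  repeat {
    bounds <- c(lo, flip_s, hi)
    lobes <- diff(bounds)
    if (!length(flip_s) || all(lobes >= min_separation_mm)) break
    shortest <- which.min(lobes)
    if (shortest == 1L) {
      flip_s <- flip_s[-1L]
    } else if (shortest == length(lobes)) {
      flip_s <- flip_s[-length(flip_s)]
    } else {
      flip_s <- flip_s[-c(shortest - 1L, shortest)]
    }
  }
  length(flip_s)
}

gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  n <- length(x)
  xp <- c(rep(x[1], r), x, rep(x[n], r)) # replicate-pad ends
  out <- stats::filter(xp, k / sum(k), sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Inflection count metric of a centerline
#'
#' Tortuosity as the number of turns along the vessel course multiplied by
#' the ratio of the actual (path) length to the direct (chord) length.
#' Under the `"paper"` convention the product uses the raw turn count, so a
#' straight vessel scores 0; the `"bullitt_plus_one"` convention uses
#' `turns + 1`, matching the classical inflection count metric, so a
#' straight vessel scores 1.
#'
#' @param cl a [centerline()].
#' @param convention `"paper"` (default) or `"bullitt_plus_one"`.
#' @param n_turns optional externally supplied turn count (e.g. analytic
#'   truth); when `NULL` it is computed with [count_turns()].
#' @param ... passed to [count_turns()].
#' @return object of class `tortuosity_metrics`: `n_turns`,
#'   `path_length_mm`, `chord_length_mm`, `length_ratio`, `icm`,
#'   `convention`.
#' @export
icm <- function(cl, convention = c("paper", "bullitt_plus_one"),
                n_turns = NULL, ...) {
  convention <- match.arg(convention)
  lp <- path_length(cl)
  lc <- chord_length(cl)
  if (lc <= 1e-9)
    stop_input("degenerate geometry: coincident endpoints (chord = 0)")
  if (is.null(n_turns)) n_turns <- count_turns(cl, ...)
  ratio <- lp / lc
  value <- if (convention == "paper") n_turns * ratio
           else (n_turns + 1L) * ratio
  structure(list(n_turns = as.integer(n_turns), path_length_mm = lp,
                 chord_length_mm = lc, length_ratio = ratio, icm = value,
                 convention = convention),
            class = "tortuosity_metrics")
}

#' @export
print.tortuosity_metrics <- function(x, ...) {
  cat(sprintf(
    "<tortuosity> turns = %d, L_path = %.2f mm, L_chord = %.2f mm, ratio = %.4f, ICM(%s) = %.4f\n",
    x$n_turns, x$path_length_mm, x$chord_length_mm, x$length_ratio,
    x$convention, x$icm))
  invisible(x)
}

#' Weighted ICM index combining carotid and vertebral tortuosity
#'
#' `0.8 * ICA_ICM + 0.2 * VA_ICM`: the weights are the approximate shares
#' of intracranial blood supply carried by the internal carotid (80%) and
#' vertebral (20%) arteries.
#'
#' @param ica_icm mean ICM of the bilateral internal carotid arteries.
#' @param va_icm mean ICM of the bilateral vertebral arteries.
#' @return the weighted index.
#' @export
icm_index <- function(ica_icm, va_icm) {
  if (any(ica_icm < 0) || any(va_icm < 0))
    stop_input("ICM values must be non-negative")
  0.8 * ica_icm + 0.2 * va_icm
}

#' Angle between the common and internal carotid arteries
#'
#' Both segments must start at their shared bifurcation point. Each
#' segment's direction is the mean unit tangent over the first `window_mm`
#' of arc length from the bifurcation; the ICA angle is the angle between
#' the two mean directions, in degrees within [0, 180].
#'
#' @param cca_segment,ica_segment [centerline()] objects whose first point
#'   is the bifurcation.
#' @param window_mm tangent-averaging window (default 10 mm).
#' @return angle in degrees.
#' @export
ica_angle <- function(cca_segment, ica_segment, window_mm = 10) {
  dir_of <- function(cl) {
    if (path_length(cl) < window_mm)
      stop_input("segment shorter than the %g mm averaging window", window_mm)
    fine <- resample_centerline(cl, window_mm / 50)
    s <- fine$cum_arc_length_mm
    keep <- which(s[-1] <= window_mm)
    seg <- diff(fine$points)[keep, , drop = FALSE]
    ut <- seg / sqrt(rowSums(seg^2))
    m <- colMeans(ut)
    m / sqrt(sum(m^2))
  }
  u <- dir_of(cca_segment)
  v <- dir_of(ica_segment)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Per-subject tortuosity summary
#'
#' Combines per-artery ICM values into the subject-level quantities used by
#' the cohort analysis: left/right arteries are averaged per territory, and
#' the territories are combined with the 0.8/0.2 supply weights.
#'
#' @param lica_icm,rica_icm,lva_icm,rva_icm per-artery ICM values.
#' @param ica_angle_deg carotid bifurcation angle in degrees, in [0, 180].
#' @return object of class `subject_tortuosity` with `ica_icm`, `va_icm`,
#'   `icm_index` and `ica_angle_deg`.
#' @export
subject_tortuosity <- function(lica_icm, rica_icm, lva_icm, rva_icm,
                               ica_angle_deg = NA_real_) {
  if (!is.na(ica_angle_deg) && (ica_angle_deg < 0 || ica_angle_deg > 180))
    stop_input("ica_angle_deg must lie in [0, 180]")
  ica <- mean(c(lica_icm, rica_icm))
  va <- mean(c(lva_icm, rva_icm))
  structure(list(ica_icm = ica, va_icm = va,
                 icm_index = icm_index(ica, va),
                 ica_angle_deg = ica_angle_deg),
            class = "subject_tortuosity")
}
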