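#' Analytic vessel course specification
#'
#' Describes a synthetic arterial course with closed-form geometry so that
#' every derived quantity (arc length, curvature, inflection count) has an
#' analytic ground truth. Three families are supported: a straight segment,
#' a planar sinusoid (axis along z, displacement along x) and a circular
#' helix (axis along z).
#'
#' @param family one of `"straight"`, `"planar_sinusoid"`, `"helix"`.
#' @param length_mm extent of the course along its axis (z), mm.
#' @param amplitude_mm sinusoid displacement amplitude, mm (sinusoid only).
#' @param periods number of full sinusoid periods over the course
#'   (sinusoid only).
#' @param helix_radius_mm,helix_pitch_mm helix radius and pitch (z advance
#'   per full turn), mm (helix only).
#' @param sample_step_mm arc-length sampling step for generated samples, mm.
#' @return an object of class `curve_spec`.
#' @export
curve_spec <- function(family = c("straight", "planar_sinusoid", "helix"),
                       length_mm, amplitude_mm = 0, periods = 0,
                       helix_radius_mm = NULL, helix_pitch_mm = NULL,
                       sample_step_mm = 0.25) {
  family <- match.arg(family)
  if (!is.numeric(length_mm) || length_mm <= 0)
    stop_input("length_mm must be positive")
  if (sample_step_mm <= 0 || sample_step_mm >= length_mm)
    stop_input("sample_step_mm must be in (0, length_mm)")
  if (family == "straight" && (amplitude_mm != 0 || periods != 0))
    stop_input("straight curves must have zero amplitude and periods")
  if (family == "planar_sinusoid" && (amplitude_mm < 0 || periods <= 0))
    stop_input("planar_sinusoid needs amplitude_mm >= 0 and periods > 0")
  if (family == "helix") {
    if (is.null(helix_radius_mm) || is.null(helix_pitch_mm) ||
        helix_radius_mm <= 0 || helix_pitch_mm <= 0)
      stop_input("helix needs positive helix_radius_mm and helix_pitch_mm")
  }
  structure(list(family = family, length_mm = length_mm,
                 amplitude_mm = amplitude_mm, periods = periods,
                 helix_radius_mm = helix_radius_mm,
                 helix_pitch_mm = helix_pitch_mm,
                 sample_step_mm = sample_step_mm),
            class = "curve_spec")
}

# position and first/second parameter derivatives at parameter t in [0, 1]
curve_eval <- function(spec, t) {
  L <- spec$length_mm
  switch(spec$family,
    straight = list(
      p  = cbind(0, 0, L * t),
      d1 = cbind(0, 0, rep(L, length(t))),
      d2 = cbind(0, 0, rep(0, length(t)))),
    planar_sinusoid = {
      w <- 2 * pi * spec$periods
      A <- spec$amplitude_mm
      list(
        p  = cbind(A * sin(w * t), 0, L * t),
        d1 = cbind(A * w * cos(w * t), 0, rep(L, length(t))),
        d2 = cbind(-A * w^2 * sin(w * t), 0, rep(0, length(t))))
    },
    helix = {
      r <- spec$helix_radius_mm
      c0 <- spec$helix_pitch_mm / (2 * pi)
      th_max <- L / c0
      th <- th_max * t
      list(
        p  = cbind(r * cos(th), r * sin(th), c0 * th),
        d1 = th_max * cbind(-r * sin(th), r * cos(th), rep(c0, length(th))),
        d2 = th_max^2 * cbind(-r * cos(th), -r * sin(th), rep(0, length(th))))
    })
}

#' Sample an analytic curve at uniform arc length
#'
#' Arc-length parameterization is obtained by numerically inverting the
#' cumulative speed integral on a dense parameter grid; positions, unit
#' tangents and curvature at the samples are then evaluated from the
#' closed-form derivatives (not by finite differences), so the output can
#' serve as an exact oracle for the discrete tortuosity pipeline.
#'
#' For the planar sinusoid the curvature is signed (sign of the in-plane
#' bending direction); its interior sign changes are the analytic inflection
#' count. For a `periods = k` sinusoid that count is `2k - 1`; for straight
#' and helical curves it is 0.
#'
#' @param spec a [curve_spec()].
#' @return list of class `analytic_curve` with `points` (n x 3 mm),
#'   `tangents` (n x 3, unit), `curvature` (1/mm, signed where defined),
#'   `arc_length_mm` (cumulative, from 0), `total_length_mm`, `n_turns`
#'   (analytic inflection count) and the `spec`.
#' @export
gen_curve <- function(spec) {
  if (!inherits(spec, "curve_spec")) stop_input("spec must be a curve_spec")
  nt <- max(4096L, ceiling(64 * spec$length_mm / spec$sample_step_mm))
  tg <- seq(0, 1, length.out = nt)
  ev <- curve_eval(spec, tg)
  sp <- sqrt(rowSums(ev$d1^2))
  # trapezoidal cumulative arc length over the dense grid
  ds <- diff(tg) * (sp[-1] + sp[-nt]) / 2
  s_cum <- c(0, cumsum(ds))
  total <- s_cum[nt]
  s_tgt <- seq(0, total, by = spec$sample_step_mm)
  if (total - s_tgt[length(s_tgt)] > 1e-9) s_tgt <- c(s_tgt, total)
  t_s <- stats::approx(s_cum, tg, xout = s_tgt, ties = "ordered")$y
  ev <- curve_eval(spec, t_s)
  d1n <- sqrt(rowSums(ev$d1^2))
  tangents <- ev$d1 / d1n
  # space-curve curvature |d1 x d2| / |d1|^3, signed for the planar family
  crossp <- cbind(ev$d1[, 2] * ev$d2[, 3] - ev$d1[, 3] * ev$d2[, 2],
                  ev$d1[, 3] * ev$d2[, 1] - ev$d1[, 1] * ev$d2[, 3],
                  ev$d1[, 1] * ev$d2[, 2] - ev$d1[, 2] * ev$d2[, 1])
  kappa <- sqrt(rowSums(crossp^2)) / d1n^3
  if (spec$family == "planar_sinusoid") {
    # bending sign in the x-z plane: sign of x'' (z'' = 0, z' > 0)
    kappa <- kappa * ifelse(crossp[, 2] >= 0, 1, -1)
  }
  n_turns <- switch(spec$family,
    straight = 0L,
    helix = 0L,
    planar_sinusoid = {
      if (spec$amplitude_mm == 0) 0L else
        sum(diff(sign(kappa[abs(kappa) > 1e-12])) != 0)
    })
  structure(list(points = ev$p, tangents = tangents, curvature = kappa,
                 arc_length_mm = s_tgt, total_length_mm = total,
                 n_turns = as.integer(n_turns), spec = spec),
            class = "analytic_curve")
}
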