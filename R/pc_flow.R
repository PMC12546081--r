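#' Generate a phase-contrast slice phantom with known flow
#'
#' Builds a magnitude/phase pair for a circular lumen with plug or
#' parabolic (Poiseuille) through-plane velocity. The phase encodes
#' velocity with the standard convention `phase = pi * v / VENC`; peak
#' velocity must stay below VENC so no aliasing occurs by construction
#' (wrapped phase is explicitly refused, not handled). The stored
#' `truth_flow_ml_min` is the discrete sum of the generated velocity field
#' over the lumen times the pixel area, so a flow quantification that uses
#' the exact lumen mask must recover it to rounding error.
#'
#' @param lumen_radius_mm lumen radius, mm.
#' @param peak_velocity_cm_s peak through-plane velocity, cm/s (may be
#'   negative for reverse flow); `|peak| < venc` required.
#' @param profile `"plug"` (uniform) or `"parabolic"`.
#' @param venc_cm_s velocity-encoding limit (default 60 cm/s, the protocol
#'   value for neck-vessel imaging).
#' @param pixel_size_mm in-plane pixel size (default 0.45 mm).
#' @param fov_mm square field of view (default fits the lumen + margin).
#' @param noise_sigma Gaussian noise SD added to the magnitude image.
#' @param seed integer seed for the noise.
#' @return object of class `pc_phantom`: `magnitude`, `phase_rad`
#'   (matrices), `lumen_mask`, `venc_cm_s`, `pixel_area_mm2`,
#'   `truth_flow_ml_min`, `truth_mean_velocity_cm_s`, generation params.
#' @export
gen_pc_phantom <- function(lumen_radius_mm, peak_velocity_cm_s,
                           profile = c("plug", "parabolic"),
                           venc_cm_s = 60, pixel_size_mm = 0.45,
                           fov_mm = NULL, noise_sigma = 0, seed = 1L,
                           lumen_intensity = 100) {
  profile <- match.arg(profile)
  if (abs(peak_velocity_cm_s) >= venc_cm_s)
    stop_input("aliasing: |peak velocity| must be < VENC (%g cm/s)", venc_cm_s)
  if (lumen_radius_mm <= 0) stop_input("lumen_radius_mm must be positive")
  if (is.null(fov_mm)) fov_mm <- 2 * lumen_radius_mm + 8 * pixel_size_mm
  n <- ceiling(fov_mm / pixel_size_mm)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_size_mm # pixel-centre coords
  r2 <- outer(ax^2, ax^2, `+`)
  inside <- r2 < lumen_radius_mm^2

  v <- matrix(0, n, n)
  if (profile == "plug") {
    v[inside] <- peak_velocity_cm_s
  } else {
    v[inside] <- peak_velocity_cm_s * (1 - r2[inside] / lumen_radius_mm^2)
  }
  phase <- pi * v / venc_cm_s
  mag <- matrix(0, n, n)
  mag[inside] <- lumen_intensity
  if (noise_sigma > 0)
    mag <- mag + with_seed(seed, matrix(rnorm(n * n, 0, noise_sigma), n, n))

  pixel_area <- pixel_size_mm^2
  # cm/s -> mm/s (x10), x mm^2 -> mm^3/s, x 60 / 1000 -> ml/min
  truth_flow <- sum(v[inside]) * 10 * pixel_area * 60 / 1000

  structure(list(magnitude = mag, phase_rad = phase, lumen_mask = inside,
                 venc_cm_s = venc_cm_s, pixel_area_mm2 = pixel_area,
                 pixel_size_mm = pixel_size_mm,
                 truth_flow_ml_min = truth_flow,
                 truth_mean_velocity_cm_s =
                   if (any(inside)) mean(v[inside]) else 0,
                 lumen_radius_mm = lumen_radius_mm, profile = profile,
                 peak_velocity_cm_s = peak_velocity_cm_s,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 lumen_intensity = lumen_intensity),
            class = "pc_phantom")
}

#' Convert phase-contrast phase to velocity
#'
#' Linear mapping `v = VENC * phase / pi` (cm/s), sign-preserving. Phase
#' outside (-pi, pi] indicates aliasing, which is out of scope and
#' refused.
#'
#' @param phase_rad numeric phase values in radians.
#' @param venc_cm_s velocity-encoding limit in cm/s.
#' @return velocities in cm/s, same shape as `phase_rad`.
#' @export
phase_to_velocity <- function(phase_rad, venc_cm_s) {
  if (venc_cm_s <= 0) stop_input("venc_cm_s must be positive")
  if (any(abs(phase_rad) > pi + 1e-12))
    stop_input("|phase| > pi: aliased phase is not supported")
  venc_cm_s * phase_rad / pi
}

#' Vessel lumen mask from a magnitude image
#'
#' Threshold at five times the background noise level, optionally
#' intersected with a user region of interest (emulating the manually
#' delineated preliminary ROI around each artery). An empty result is a
#' valid mask flagged `empty`.
#'
#' @param magnitude 2D magnitude matrix.
#' @param noise_level background noise SD (> 0), e.g. from
#'   [estimate_noise()] on a corner region.
#' @param roi optional logical matrix restricting the search.
#' @param k threshold multiplier (default 5).
#' @return list with `mask` (logical matrix), `threshold`, `empty`.
#' @export
pc_vessel_mask <- function(magnitude, noise_level, roi = NULL, k = 5) {
  if (!is.matrix(magnitude)) stop_input("magnitude must be a 2D matrix")
  if (!is.numeric(noise_level) || noise_level <= 0)
    stop_input("noise_level must be positive")
  thr <- k * noise_level
  m <- magnitude >= thr
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(magnitude)))
      stop_input("roi shape does not match the magnitude image")
    m <- m & (roi != 0)
  }
  list(mask = m, threshold = thr, empty = !any(m))
}

#' Blood flow from a phase-contrast slice
#'
#' Velocities inside the vessel mask are summed and converted to a
#' volumetric flow: `sum(v [cm/s]) * 10 * pixel_area [mm^2]` gives mm^3/s,
#' times 60/1000 gives ml/min. The sign of the velocities is preserved, so
#' reverse flow yields a negative contribution.
#'
#' @param slice a `pc_phantom` or a list with `phase_rad`, `venc_cm_s`,
#'   `pixel_area_mm2`.
#' @param mask logical matrix of lumen pixels (e.g. from
#'   [pc_vessel_mask()]); defaults to the phantom's own lumen mask.
#' @return flow in ml/min.
#' @export
flow_from_slice <- function(slice, mask = NULL) {
  if (is.null(mask)) mask <- slice$lumen_mask
  if (is.null(mask)) stop_input("no mask supplied and slice carries none")
  if (!identical(dim(mask), dim(slice$phase_rad)))
    stop_input("mask shape does not match the phase image")
  if (!any(mask)) stop_input("mask is empty")
  v <- phase_to_velocity(slice$phase_rad[mask], slice$venc_cm_s)
  sum(v) * 10 * slice$pixel_area_mm2 * 60 / 1000
}

#' Parenchyma-normalized global cerebral blood flow
#'
#' Sums the flows of the four brain-feeding arteries and normalizes to the
#' parenchymal mass, approximated as `1.06 g/ml x (GM + WM volume)`:
#' `CBF = total_flow / (1.06 * (vol_gm + vol_wm)) * 100` in ml/100 g/min.
#'
#' @param per_artery_flows named numeric vector with exactly the entries
#'   `LICA`, `RICA`, `LVA`, `RVA` (ml/min).
#' @param vol_gm_ml,vol_wm_ml gray/white matter volumes, ml (> 0).
#' @return object of class `flow_result`: `per_artery_flow_ml_min`,
#'   `total_flow_ml_min`, `vol_gm_ml`, `vol_wm_ml`,
#'   `normalized_cbf_ml_100g_min`, `brain_density_g_ml` (1.06).
#' @export
normalized_cbf <- function(per_artery_flows, vol_gm_ml, vol_wm_ml) {
  arteries <- c("LICA", "RICA", "LVA", "RVA")
  missing <- setdiff(arteries, names(per_artery_flows))
  if (length(missing))
    stop_input("missing artery flow(s): %s", paste(missing, collapse = ", "))
  if (vol_gm_ml <= 0 || vol_wm_ml <= 0)
    stop_input("parenchymal volumes must be positive")
  flows <- per_artery_flows[arteries]
  total <- sum(flows)
  dens <- 1.06
  cbf <- total / (dens * (vol_gm_ml + vol_wm_ml)) * 100
  structure(list(per_artery_flow_ml_min = flows, total_flow_ml_min = total,
                 vol_gm_ml = vol_gm_ml, vol_wm_ml = vol_wm_ml,
                 normalized_cbf_ml_100g_min = cbf,
                 brain_density_g_ml = dens),
            class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> total = %.1f ml/min, normalized CBF = %.2f ml/100g/min\n",
              x$total_flow_ml_min, x$normalized_cbf_ml_100g_min))
  invisible(x)
}
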