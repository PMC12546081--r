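#' Consensus single-delay pcASL quantification parameters
#'
#' Defaults are the standard 3T single-PLD protocol values: brain/blood
#' partition coefficient lambda = 0.9 ml/g, labeling efficiency
#' alpha = 0.85, label duration tau = 1800 ms, post-labeling delay
#' PLD = 2000 ms, arterial blood T1 = 1650 ms.
#'
#' @param lambda_ml_g,alpha,tau_ms,pld_ms,t1_blood_ms see description.
#' @return object of class `asl_params`.
#' @export
asl_params <- function(lambda_ml_g = 0.9, alpha = 0.85, tau_ms = 1800,
                       pld_ms = 2000, t1_blood_ms = 1650) {
  vals <- c(lambda_ml_g, alpha, tau_ms, pld_ms, t1_blood_ms)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_input("all ASL parameters must be positive")
  structure(list(lambda_ml_g = lambda_ml_g, alpha = alpha, tau_ms = tau_ms,
                 pld_ms = pld_ms, t1_blood_ms = t1_blood_ms),
            class = "asl_params")
}

# scalar quantification factor: CBF = factor * dM / M0, in ml/100 g/min.
# Times are converted to seconds inside the formula; with the 6000
# prefactor (ml/g -> ml/100 g, 1/s -> 1/min) the result is ml/100 g/min.
asl_cbf_factor <- function(params) {
  t1 <- params$t1_blood_ms / 1000
  pld <- params$pld_ms / 1000
  tau <- params$tau_ms / 1000
  6000 * params$lambda_ml_g * exp(pld / t1) /
    (2 * params$alpha * t1 * (1 - exp(-tau / t1)))
}

#' Generate an ASL phantom by inverting the consensus quantification
#'
#' Constructs control/label/M0 volumes such that applying [asl_cbf()] with
#' the same parameters recovers `truth_cbf` exactly (to floating point):
#' the perfusion-weighted difference is
#' `dM = truth_cbf * M0 / factor(params)`, added on top of a common
#' baseline, so `control - label = dM` by construction.
#'
#' @param truth_cbf a [voxel_grid()] (or array) of CBF in ml/100 g/min,
#'   non-negative.
#' @param params an [asl_params()].
#' @param m0 equilibrium magnetization map (scalar or array; default 1000);
#'   must be positive wherever `truth_cbf > 0`.
#' @param baseline_frac baseline tissue signal as a fraction of M0
#'   (default 0.3, emulating background-suppressed acquisitions).
#' @return object of class `asl_phantom`: `control`, `label`, `m0`
#'   ([voxel_grid()]s), `truth_cbf`, `params`.
#' @export
gen_asl_phantom <- function(truth_cbf, params = asl_params(), m0 = 1000,
                            baseline_frac = 0.3) {
  if (!inherits(truth_cbf, "voxel_grid")) truth_cbf <- voxel_grid(truth_cbf, 1)
  cbf <- truth_cbf$values
  if (any(cbf < 0)) stop_input("truth_cbf must be non-negative")
  if (length(m0) == 1L) m0 <- array(m0, dim(cbf))
  if (!identical(dim(m0), dim(cbf))) stop_input("m0 shape mismatch")
  if (any(m0 <= 0 & cbf > 0))
    stop_input("m0 must be positive wherever truth_cbf > 0")
  dM <- cbf * m0 / asl_cbf_factor(params)
  base <- baseline_frac * m0
  mk <- function(v) voxel_grid(v, truth_cbf$spacing_mm, truth_cbf$origin_mm)
  structure(list(control = mk(base + dM), label = mk(base), m0 = mk(m0),
                 truth_cbf = truth_cbf, params = params),
            class = "asl_phantom")
}

#' Voxelwise CBF from pcASL control/label/M0 volumes
#'
#' Consensus single-delay quantification:
#' `CBF = 6000 lambda dM exp(PLD/T1b) / (2 alpha T1b M0 (1 - exp(-tau/T1b)))`
#' in ml/100 g/min, with the times in seconds inside the formula. The
#' perfusion-weighted difference defaults to `control - label` (positive
#' perfusion signal); set `sign = "label_minus_control"` if the inputs
#' follow the opposite subtraction order. Voxels with `m0 <= 0` are
#' undefined (`NA`).
#'
#' @param control,label,m0 [voxel_grid()]s (or arrays) of matching shape.
#' @param params an [asl_params()].
#' @param sign subtraction convention for the difference image.
#' @return object of class `cbf_result`: `cbf_map` ([voxel_grid()], NA
#'   where undefined) and `params`.
#' @export
asl_cbf <- function(control, label, m0, params = asl_params(),
                    sign = c("control_minus_label", "label_minus_control")) {
  sign <- match.arg(sign)
  as_grid <- function(x) if (inherits(x, "voxel_grid")) x else voxel_grid(x, 1)
  control <- as_grid(control); label <- as_grid(label); m0 <- as_grid(m0)
  assert_same_geometry(control, label, "control/label")
  assert_same_geometry(control, m0, "control/m0")
  if (all(m0$values <= 0)) stop_input("m0 is non-positive everywhere")
  dM <- control$values - label$values
  if (sign == "label_minus_control") dM <- -dM
  cbf <- asl_cbf_factor(params) * dM / m0$values
  cbf[m0$values <= 0] <- NA_real_
  structure(list(cbf_map = voxel_grid(cbf, control$spacing_mm,
                                      control$origin_mm),
                 params = params),
            class = "cbf_result")
}

#' Mean parenchymal CBF over gray + white matter
#'
#' Arithmetic mean of the CBF map over the union of the gray- and
#' white-matter masks, excluding undefined (NA) voxels.
#'
#' @param cbf_map a [voxel_grid()] (or the `cbf_result` from [asl_cbf()]).
#' @param gm_mask,wm_mask binary arrays aligned with the map.
#' @return mean CBF in ml/100 g/min; also reports `n_used` as an attribute.
#' @export
mean_parenchymal_cbf <- function(cbf_map, gm_mask, wm_mask) {
  if (inherits(cbf_map, "cbf_result")) cbf_map <- cbf_map$cbf_map
  vals <- if (inherits(cbf_map, "voxel_grid")) cbf_map$values else cbf_map
  sel <- (gm_mask != 0) | (wm_mask != 0)
  if (!identical(dim(sel), dim(vals))) stop_input("mask shape mismatch")
  sel <- sel & !is.na(vals)
  if (!any(sel)) stop_input("parenchyma mask is empty (or fully undefined)")
  out <- mean(vals[sel])
  attr(out, "n_used") <- sum(sel)
  out
}
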