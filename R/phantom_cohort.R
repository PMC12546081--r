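#' Synthetic cohort specification
#'
#' Declares the simulated-population parameters of the cohort generator.
#' Demographic and clinical scales default to the elderly WMH-cohort
#' setting the pipeline targets (mean age 73.1 +/- 5.5 y, 42/75 female,
#' systolic/diastolic BP 131.1 +/- 16.4 / 70.4 +/- 11.8 mmHg,
#' BMI 25.6 +/- 4.5), and the planted dependence structure defaults to the
#' reported effects: an ICM-index/normalized-CBF partial correlation of
#' -0.35 given age and sex, a severe-vs-mild ICM-index group shift of 2.25,
#' and a lesion-volume regression slope of 1.2 cm^3 per ICM-index unit.
#'
#' @param n_subjects number of subjects (>= 8).
#' @param target_partial_r_icm_cbf planted partial correlation between ICM
#'   index and normalized CBF given age and sex, in (-1, 1).
#' @param group_effect_icm severe-minus-mild shift of the ICM index.
#' @param beta_icm_lesion lesion-volume slope on ICM index (cm^3 per unit).
#' @param beta_age_lesion lesion-volume slope on age (cm^3 per year).
#' @param lesion_noise_sd residual SD of lesion volume (cm^3).
#' @param seed integer seed.
#' @param missing_bp_frac fraction of subjects without BP measurements
#'   (default 10/75, as in a realistic partially measured covariate).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 75L, target_partial_r_icm_cbf = -0.35,
                        group_effect_icm = 2.25, beta_icm_lesion = 1.2,
                        beta_age_lesion = 0.4, lesion_noise_sd = 5,
                        seed = 1L, missing_bp_frac = 10 / 75) {
  if (n_subjects < 8L) stop_input("n_subjects must be >= 8")
  if (abs(target_partial_r_icm_cbf) >= 1)
    stop_input("|target_partial_r_icm_cbf| must be < 1")
  if (lesion_noise_sd < 0) stop_input("lesion_noise_sd must be non-negative")
  structure(list(n_subjects = as.integer(n_subjects),
                 target_partial_r_icm_cbf = target_partial_r_icm_cbf,
                 group_effect_icm = group_effect_icm,
                 beta_icm_lesion = beta_icm_lesion,
                 beta_age_lesion = beta_age_lesion,
                 lesion_noise_sd = lesion_noise_sd,
                 seed = as.integer(seed),
                 missing_bp_frac = missing_bp_frac),
            class = "cohort_spec")
}

#' Generate a synthetic per-subject cohort table
#'
#' Draws demographics from the stated normal/Bernoulli distributions,
#' assigns WMH severity groups with the sex-dependent prevalence of the
#' target setting, and plants the requested dependence structure:
#'
#' * the ICM index gets a group shift plus age loading;
#' * normalized CBF is built so that its residual (given age and sex)
#'   correlates with the ICM-index residual at exactly the target partial
#'   correlation in expectation (the ICM residual is computed by empirical
#'   projection, so the large-n estimate converges to the target);
#' * total lesion volume follows a linear model in ICM index and age plus
#'   Gaussian noise (deliberately *not* floored at zero, so least-squares
#'   recovery of the planted slope is unbiased);
#' * periventricular/deep volumes split the total 80/20 and always sum to
#'   it; pcASL CBF is a noisy correlate of normalized CBF (r ~ 0.63).
#'
#' Identical `(spec, seed)` give an identical table.
#'
#' @param spec a [cohort_spec()].
#' @return `data.frame` with columns `id`, `age`, `sex` ("F"/"M"),
#'   `systolic_bp`, `diastolic_bp` (NA when unmeasured), `bmi`, `group`
#'   ("mild"/"severe"), `lesion_total_cm3`, `lesion_pvwm_cm3`,
#'   `lesion_dwm_cm3`, `icm_index`, `ica_angle_deg`, `normalized_cbf`,
#'   `asl_cbf`.
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  if (!inherits(spec, "cohort_spec")) stop_input("spec must be a cohort_spec")
  n <- spec$n_subjects
  with_seed(spec$seed, {
    age <- rnorm(n, 73.1, 5.5)
    sexF <- rbinom(n, 1L, 42 / 75)
    sbp <- rnorm(n, 131.1, 16.4)
    dbp <- rnorm(n, 70.4, 11.8)
    bmi <- rnorm(n, 25.6, 4.5)
    miss <- runif(n) < spec$missing_bp_frac
    sbp[miss] <- NA_real_
    dbp[miss] <- NA_real_

    # severity more prevalent in females (25/42 vs 11/33)
    p_sev <- ifelse(sexF == 1L, 25 / 42, 11 / 33)
    severe <- rbinom(n, 1L, p_sev)

    zage <- (age - 73.1) / 5.5
    icm_resid_sd <- 1.2
    icm <- 5.08 + spec$group_effect_icm * severe + 0.35 * zage +
      rnorm(n, 0, icm_resid_sd)
    icm <- pmax(icm, 0.1) # tortuosity is non-negative

    # residualize ICM on [1, age, sexF] empirically, then mix in the CBF
    # residual at the target partial correlation
    u <- stats::lm.fit(cbind(1, age, sexF), icm)$residuals
    us <- u / stats::sd(u)
    rho <- spec$target_partial_r_icm_cbf
    z <- rnorm(n)
    cbf_resid <- rho * us + sqrt(1 - rho^2) * z
    cbf <- 39.53 - 1.5 * zage - 0.5 * sexF + 7.0 * cbf_resid

    lesion <- -31.5 + spec$beta_icm_lesion * icm +
      spec$beta_age_lesion * age + rnorm(n, 0, spec$lesion_noise_sd)
    pv_frac <- pmin(pmax(rnorm(n, 0.8, 0.05), 0.5), 0.98)
    pv <- pv_frac * lesion
    dw <- lesion - pv

    angle <- 56.35 + 14.96 * (0.3 * us + sqrt(1 - 0.3^2) * rnorm(n))
    angle <- pmin(pmax(angle, 0), 180)

    asl <- 38.52 + 10.22 * (0.63 * scale(cbf)[, 1] +
                              sqrt(1 - 0.63^2) * rnorm(n))

    data.frame(
      id = sprintf("S%04d", seq_len(n)),
      age = age,
      sex = factor(ifelse(sexF == 1L, "F", "M"), levels = c("F", "M")),
      systolic_bp = sbp, diastolic_bp = dbp, bmi = bmi,
      group = factor(ifelse(severe == 1L, "severe", "mild"),
                     levels = c("mild", "severe")),
      lesion_total_cm3 = lesion, lesion_pvwm_cm3 = pv,
      lesion_dwm_cm3 = dw,
      icm_index = icm, ica_angle_deg = angle,
      normalized_cbf = cbf, asl_cbf = asl,
      stringsAsFactors = FALSE)
  })
}
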