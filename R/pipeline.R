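#' Pipeline configuration
#'
#' Central bag of tunables for the end-to-end flow. Unknown keys are
#' rejected, and a configuration round-trips unchanged through its JSON
#' serialization ([write_config()] / [read_config()]).
#'
#' @param ... overrides of the defaults listed below.
#' @return object of class `pipeline_config`.
#' @section Keys:
#' * `tof_threshold_frac` (0.5): segmentation threshold as a fraction of
#'   the tube foreground intensity.
#' * `connectivity` (18): component connectivity for masks.
#' * `centerline_step_mm` (0.5), `medialness_power` (2).
#' * `icm_convention` ("paper"), `kappa_min` (1e-3),
#'   `turn_min_separation_mm` (5), `turn_trim_mm` (4).
#' * `angle_window_mm` (10).
#' * `venc_cm_s` (60), `pc_noise_k` (5).
#' * `asl`: list of [asl_params()] values.
#' * `pv_dwm_threshold_mm` (13).
#' * `alpha` (0.05), `t_var_equal` (FALSE).
#' * `seed` (1).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    tof_threshold_frac = 0.5,
    connectivity = 18L,
    centerline_step_mm = 0.5,
    medialness_power = 2,
    icm_convention = "paper",
    kappa_min = 1e-3,
    turn_min_separation_mm = 5,
    turn_trim_mm = 4,
    angle_window_mm = 10,
    venc_cm_s = 60,
    pc_noise_k = 5,
    asl = unclass(asl_params()),
    pv_dwm_threshold_mm = 13,
    alpha = 0.05,
    t_var_equal = FALSE,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  cfg$version <- as.character(utils::packageVersion("tortuflow"))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  version <- raw$version
  raw$version <- NULL
  cfg <- do.call(pipeline_config, raw)
  cfg$version <- version %||% cfg$version
  cfg
}

#' Run the full per-subject pipeline on phantom (or ingested) inputs
#'
#' Executes, per enabled input: segmentation -> centerline -> tortuosity
#' for each supplied artery; phase-contrast flow per artery and
#' parenchyma-normalized CBF; ASL CBF; lesion classification and volumes.
#' A failing stage does not abort the subject: the affected fields stay NA
#' and the failure is recorded in `exclusions` (the analysis-level analog
#' of excluding an artery whose centerline tracking failed).
#'
#' @param config a [pipeline_config()].
#' @param inputs list with optional elements:
#'   * `arteries`: named list (`LICA`, `RICA`, `LVA`, `RVA`) of
#'     `tube_phantom` objects.
#'   * `cca`, `ica`: [centerline()] segments sharing the bifurcation, for
#'     the ICA angle.
#'   * `pc_slices`: named list per artery of `pc_phantom` objects.
#'   * `vol_gm_ml`, `vol_wm_ml`: parenchymal volumes.
#'   * `asl`: an `asl_phantom` (or list with `control`, `label`, `m0`),
#'     plus optional `gm_mask`/`wm_mask`.
#'   * `lesions`: a `lesion_scene` (or list with `lesion_mask`,
#'     `ventricle_mask`).
#' @param id subject identifier.
#' @return list of class `subject_record`: `id`, `metrics` (one-row data
#'   frame), `per_artery` (ICM table), `exclusions` (character),
#'   `provenance` (config hash, version, seed).
#' @export
run_subject <- function(config, inputs, id = "subject") {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must be a pipeline_config")
  excl <- character(0)
  note <- function(stage, e)
    sprintf("%s: %s", stage, conditionMessage(e))

  artery_icm <- c(LICA = NA_real_, RICA = NA_real_,
                  LVA = NA_real_, RVA = NA_real_)
  per_artery <- list()
  if (!is.null(inputs$arteries)) {
    for (a in names(inputs$arteries)) {
      res <- tryCatch({
        ph <- inputs$arteries[[a]]
        thr <- config$tof_threshold_frac * ph$foreground_intensity
        seg <- threshold_segment(ph$volume, thr,
                                 connectivity = config$connectivity)
        src <- round(physical_to_index(ph$volume,
                                       ph$truth_centerline$points[1, ]))
        seg1 <- select_component(seg, src)
        cl <- extract_centerline(seg1, src,
                                 step_mm = config$centerline_step_mm,
                                 medialness_power = config$medialness_power)
        icm(cl, convention = config$icm_convention,
            kappa_min = config$kappa_min,
            min_separation_mm = config$turn_min_separation_mm,
            trim_mm = config$turn_trim_mm)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        excl <- c(excl, note(paste0("tortuosity/", a), res))
      } else {
        artery_icm[[a]] <- res$icm
        per_artery[[a]] <- data.frame(
          artery = a, n_turns = res$n_turns,
          path_length_mm = res$path_length_mm,
          chord_length_mm = res$chord_length_mm,
          length_ratio = res$length_ratio, icm = res$icm,
          stringsAsFactors = FALSE)
      }
    }
  }
  angle <- NA_real_
  if (!is.null(inputs$cca) && !is.null(inputs$ica)) {
    res <- tryCatch(
      ica_angle(inputs$cca, inputs$ica, window_mm = config$angle_window_mm),
      error = function(e) e)
    if (inherits(res, "error")) excl <- c(excl, note("ica_angle", res))
    else angle <- res
  }
  icm_idx <- if (all(!is.na(artery_icm)))
    icm_index(mean(artery_icm[c("LICA", "RICA")]),
              mean(artery_icm[c("LVA", "RVA")]))
  else NA_real_

  flows <- c(LICA = NA_real_, RICA = NA_real_, LVA = NA_real_,
             RVA = NA_real_)
  ncbf <- NA_real_
  if (!is.null(inputs$pc_slices)) {
    for (a in names(inputs$pc_slices)) {
      res <- tryCatch({
        sl <- inputs$pc_slices[[a]]
        noise <- if (sl$noise_sigma > 0) {
          corner <- corner_region(dim(sl$magnitude))
          estimate_noise(array(sl$magnitude, c(dim(sl$magnitude), 1L)),
                         array(corner, c(dim(corner), 1L)))
        } else NA
        mask <- if (is.finite(noise) && noise > 0)
          pc_vessel_mask(sl$magnitude, noise, k = config$pc_noise_k)$mask
        else sl$lumen_mask
        flow_from_slice(sl, mask)
      }, error = function(e) e)
      if (inherits(res, "error")) excl <- c(excl, note(paste0("pcflow/", a), res))
      else flows[[a]] <- res
    }
    if (all(!is.na(flows)) && !is.null(inputs$vol_gm_ml) &&
        !is.null(inputs$vol_wm_ml)) {
      res <- tryCatch(
        normalized_cbf(flows, inputs$vol_gm_ml, inputs$vol_wm_ml),
        error = function(e) e)
      if (inherits(res, "error")) excl <- c(excl, note("normalized_cbf", res))
      else ncbf <- res$normalized_cbf_ml_100g_min
    }
  }

  aslv <- NA_real_
  if (!is.null(inputs$asl)) {
    res <- tryCatch({
      ph <- inputs$asl
      cb <- asl_cbf(ph$control, ph$label, ph$m0,
                    params = do.call(asl_params, config$asl))
      gm <- inputs$gm_mask %||% (ph$m0$values > 0)
      wm <- inputs$wm_mask %||% array(FALSE, dim(ph$m0$values))
      mean_parenchymal_cbf(cb, gm, wm)
    }, error = function(e) e)
    if (inherits(res, "error")) excl <- c(excl, note("asl", res))
    else aslv <- as.numeric(res)
  }

  lv <- list(total_cm3 = NA_real_, pvwm_cm3 = NA_real_, dwm_cm3 = NA_real_)
  if (!is.null(inputs$lesions)) {
    res <- tryCatch({
      sc <- inputs$lesions
      comp <- lesion_components(sc$lesion_mask,
                                connectivity = config$connectivity)
      comp <- distance_to_ventricle(comp, sc$ventricle_mask)
      comp <- classify_pv_dwm(comp,
                              threshold_mm = config$pv_dwm_threshold_mm)
      lesion_volumes(comp)
    }, error = function(e) e)
    if (inherits(res, "error")) excl <- c(excl, note("lesions", res))
    else lv <- res
  }

  metrics <- data.frame(
    id = id,
    lica_icm = artery_icm[["LICA"]], rica_icm = artery_icm[["RICA"]],
    lva_icm = artery_icm[["LVA"]], rva_icm = artery_icm[["RVA"]],
    icm_index = icm_idx, ica_angle_deg = angle,
    flow_lica = flows[["LICA"]], flow_rica = flows[["RICA"]],
    flow_lva = flows[["LVA"]], flow_rva = flows[["RVA"]],
    normalized_cbf = ncbf, asl_cbf = aslv,
    lesion_total_cm3 = lv$total_cm3, lesion_pvwm_cm3 = lv$pvwm_cm3,
    lesion_dwm_cm3 = lv$dwm_cm3,
    stringsAsFactors = FALSE)

  structure(list(
    id = id, metrics = metrics,
    per_artery = if (length(per_artery)) do.call(rbind, per_artery) else NULL,
    exclusions = excl,
    provenance = list(config_hash = config_hash(unclass(config)),
                      version = config$version, seed = config$seed)),
    class = "subject_record")
}

corner_region <- function(d, frac = 0.12) {
  k <- pmax(2L, floor(d * frac))
  m <- matrix(FALSE, d[1], d[2])
  m[c(1:k[1], (d[1] - k[1] + 1):d[1]), c(1:k[2], (d[2] - k[2] + 1):d[2])] <- TRUE
  m
}

#' Cohort-level statistical report
#'
#' Runs the paper-style analysis plan on a per-subject table: normality-
#' gated mild/severe group comparisons (BH-FDR adjusted within the block),
#' the sex-by-severity chi-square, partial correlations of the tortuosity
#' metrics with normalized CBF controlling for age and sex (BH-FDR within
#' the block), the three lesion regression models, per-sex lesion-on-CBF
#' slopes, and success-rate accounting. Analyses whose preconditions fail
#' (e.g. insufficient group sizes) are skipped with a log entry rather than
#' aborting the report.
#'
#' @param config a [pipeline_config()].
#' @param table cohort `data.frame` in the [gen_cohort()] layout.
#' @return list of class `cohort_report` with `group_comparisons`,
#'   `sex_chi_square`, `partial_correlations`, `regressions`, `sex_slopes`,
#'   `accounting`, `skipped`, `provenance`.
#' @export
run_cohort <- function(config, table) {
  if (!inherits(config, "pipeline_config"))
    stop_input("config must be a pipeline_config")
  skipped <- character(0)
  vars <- intersect(c("age", "bmi", "systolic_bp", "diastolic_bp",
                      "lesion_total_cm3", "icm_index", "ica_angle_deg",
                      "normalized_cbf", "asl_cbf"), names(table))
  ok_groups <- "group" %in% names(table) &&
    all(table(table$group) >= 3)
  gc_tab <- NULL
  if (ok_groups) {
    rows <- lapply(vars, function(v) {
      res <- tryCatch(
        compare_groups(table[[v]], table$group,
                       var_equal = config$t_var_equal,
                       alpha = config$alpha),
        error = function(e) e)
      if (inherits(res, "error")) {
        skipped <<- c(skipped, sprintf("group_comparison/%s: %s", v,
                                       conditionMessage(res)))
        return(NULL)
      }
      data.frame(variable = v, test = res$test_name,
                 statistic = res$statistic, p_value = res$p_value,
                 n_used = res$n_used, stringsAsFactors = FALSE)
    })
    gc_tab <- do.call(rbind, rows)
    if (!is.null(gc_tab)) gc_tab$p_adjusted <- bh_fdr(gc_tab$p_value)
  } else skipped <- c(skipped, "group_comparisons: need >= 3 subjects per group")

  chi <- NULL
  if (ok_groups && "sex" %in% names(table)) {
    counts <- table(table$sex, table$group)
    chi <- tryCatch(chi_square_2x2(counts), error = function(e) {
      skipped <<- c(skipped, sprintf("sex_chi_square: %s", conditionMessage(e)))
      NULL
    })
  }

  pc_tab <- NULL
  if (all(c("age", "sex", "normalized_cbf") %in% names(table))) {
    cov <- data.frame(age = table$age,
                      sex = as.numeric(table$sex == "F"))
    pairs <- list(c("icm_index", "normalized_cbf"),
                  c("ica_angle_deg", "normalized_cbf"),
                  c("normalized_cbf", "lesion_total_cm3"),
                  c("asl_cbf", "lesion_total_cm3"))
    rows <- lapply(pairs, function(pp) {
      if (!all(pp %in% names(table))) return(NULL)
      res <- tryCatch(partial_correlation(table[[pp[1]]], table[[pp[2]]], cov),
                      error = function(e) e)
      if (inherits(res, "error")) {
        skipped <<- c(skipped, sprintf("partial/%s~%s: %s", pp[1], pp[2],
                                       conditionMessage(res)))
        return(NULL)
      }
      data.frame(x = pp[1], y = pp[2], r = res$statistic,
                 p_value = res$p_value, n_used = res$n_used,
                 stringsAsFactors = FALSE)
    })
    pc_tab <- do.call(rbind, rows)
    if (!is.null(pc_tab)) pc_tab$p_adjusted <- bh_fdr(pc_tab$p_value)
  }

  regs <- lapply(c(total = "total", PVWM = "PVWM", DWM = "DWM"),
                 function(o) tryCatch(wmh_regression(table, o),
                                      error = function(e) {
                   skipped <<- c(skipped, sprintf("regression/%s: %s", o,
                                                  conditionMessage(e)))
                   NULL
                 }))

  slopes <- tryCatch(sex_slopes(table), error = function(e) {
    skipped <<- c(skipped, sprintf("sex_slopes: %s", conditionMessage(e)))
    NULL
  })

  n <- nrow(table)
  n_icm <- sum(!is.na(table$icm_index))
  structure(list(
    group_comparisons = gc_tab, sex_chi_square = chi,
    partial_correlations = pc_tab, regressions = regs,
    sex_slopes = slopes,
    accounting = list(n_subjects = n, n_with_icm = n_icm,
                      success_rate = n_icm / n),
    skipped = skipped,
    provenance = list(config_hash = config_hash(unclass(config)),
                      version = config$version, seed = config$seed)),
    class = "cohort_report")
}

#' Serialize a cohort report to JSON
#' @param report a `cohort_report`.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  ser <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE, na = "null")
  invisible(path)
}
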