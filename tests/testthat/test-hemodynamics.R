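test_that("phase maps linearly to velocity under the VENC convention", {
  expect_equal(phase_to_velocity(pi, 60), 60)
  expect_equal(phase_to_velocity(0, 60), 0)
  expect_equal(phase_to_velocity(pi / 2, 60), 30)
  expect_equal(phase_to_velocity(-pi / 2, 60), -30)
  expect_error(phase_to_velocity(3.5, 60), "aliased")
})

test_that("pc_vessel_mask applies the five-times-noise rule", {
  ph <- gen_pc_phantom(3, 10, "plug", pixel_size_mm = 0.45,
                       lumen_intensity = 100)
  mk <- pc_vessel_mask(ph$magnitude, noise_level = 5)
  expect_equal(mk$threshold, 25)
  expect_identical(mk$mask, ph$lumen_mask)
  # threshold above the lumen -> empty
  mk2 <- pc_vessel_mask(ph$magnitude, noise_level = 21)
  expect_true(mk2$empty)
  # ROI excluding the lumen -> empty regardless of intensity
  roi <- matrix(FALSE, nrow(ph$magnitude), ncol(ph$magnitude))
  roi[1:2, 1:2] <- TRUE
  expect_true(pc_vessel_mask(ph$magnitude, 5, roi = roi)$empty)
  expect_error(pc_vessel_mask(ph$magnitude, 0), "positive")
})

test_that("flow_from_slice recovers analytic and discrete truths", {
  ph <- gen_pc_phantom(3, 10, "plug", pixel_size_mm = 0.45)
  expect_equal(flow_from_slice(ph), 169.646, tolerance = 0.1 * 169.646)
  pb <- gen_pc_phantom(4, 25, "parabolic", pixel_size_mm = 0.45)
  expect_equal(flow_from_slice(pb), pb$truth_flow_ml_min, tolerance = 1e-9)
  # sign symmetry: reversed flow is equal and opposite
  pn <- gen_pc_phantom(3, -10, "plug", pixel_size_mm = 0.45)
  expect_equal(flow_from_slice(pn), -flow_from_slice(ph), tolerance = 1e-9)
  expect_error(flow_from_slice(ph, matrix(FALSE, 2, 2)), "shape")
})

test_that("flow error shrinks with pixel size across radii 2-6 mm", {
  mean_err <- vapply(c(1.2, 0.8, 0.45), function(px) {
    errs <- vapply(2:6, function(r) {
      p <- gen_pc_phantom(r, 10, "plug", pixel_size_mm = px)
      truth <- 10 * 10 * pi * r^2 * 60 / 1000
      abs(p$truth_flow_ml_min - truth) / truth
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_err) < 0))
  expect_lt(mean_err[3], 0.10)
})

test_that("normalized_cbf implements the parenchymal-mass normalization", {
  flows <- c(LICA = 300, RICA = 250, LVA = 120, RVA = 80)
  fr <- normalized_cbf(flows, vol_gm_ml = 700, vol_wm_ml = 500)
  expect_equal(fr$total_flow_ml_min, 750)
  expect_equal(fr$normalized_cbf_ml_100g_min, 750 / (1.06 * 1200) * 100)
  expect_equal(fr$normalized_cbf_ml_100g_min, 58.96, tolerance = 0.01)
  # homogeneity: doubling the volumes halves the CBF
  fr2 <- normalized_cbf(flows, 1400, 1000)
  expect_equal(fr2$normalized_cbf_ml_100g_min,
               fr$normalized_cbf_ml_100g_min / 2)
  # depends only on the artery sum
  relab <- c(LICA = 80, RICA = 120, LVA = 250, RVA = 300)
  expect_equal(normalized_cbf(relab, 700, 500)$normalized_cbf_ml_100g_min,
               fr$normalized_cbf_ml_100g_min)
  expect_equal(normalized_cbf(flows * 0, 700, 500)$normalized_cbf_ml_100g_min,
               0)
  expect_error(normalized_cbf(flows[-2], 700, 500), "RICA")
})

test_that("asl_cbf matches an independent scalar evaluation", {
  # dM/M0 = 0.005 with the default parameter set, hand-evaluated
  hand <- 6000 * 0.9 * 0.005 * exp(2.0 / 1.65) /
    (2 * 0.85 * 1.65 * (1 - exp(-1.8 / 1.65)))
  m0 <- voxel_grid(array(1000, c(2, 2, 2)), 1)
  ctrl <- voxel_grid(array(305, c(2, 2, 2)), 1)
  lab <- voxel_grid(array(300, c(2, 2, 2)), 1)
  out <- asl_cbf(ctrl, lab, m0)
  expect_equal(unname(out$cbf_map$values[1, 1, 1]), hand, tolerance = 1e-12)
  # linear in dM
  ctrl2 <- voxel_grid(array(310, c(2, 2, 2)), 1)
  expect_equal(asl_cbf(ctrl2, lab, m0)$cbf_map$values[1, 1, 1], 2 * hand,
               tolerance = 1e-12)
  # sign convention flag
  out_rev <- asl_cbf(lab, ctrl, m0, sign = "label_minus_control")
  expect_equal(out_rev$cbf_map$values, out$cbf_map$values)
  # dM = 0 -> 0; m0 <= 0 -> undefined
  expect_equal(asl_cbf(lab, lab, m0)$cbf_map$values[1, 1, 1], 0)
  m0z <- voxel_grid(array(c(0, rep(1000, 7)), c(2, 2, 2)), 1)
  outz <- asl_cbf(ctrl, lab, m0z)
  expect_true(is.na(outz$cbf_map$values[1, 1, 1]))
  expect_error(asl_cbf(ctrl, lab, voxel_grid(array(0, c(2, 2, 2)), 1)),
               "non-positive")
})

test_that("mean_parenchymal_cbf averages GM+WM and skips undefined", {
  v <- array(50, c(4, 4, 2))
  g <- voxel_grid(v, 1)
  gm <- array(FALSE, dim(v)); gm[1:2, , ] <- TRUE
  wm <- array(FALSE, dim(v)); wm[3:4, , ] <- TRUE
  expect_equal(as.numeric(mean_parenchymal_cbf(g, gm, wm)), 50)
  v2 <- v; v2[gm] <- 40; v2[wm] <- 60
  expect_equal(as.numeric(mean_parenchymal_cbf(voxel_grid(v2, 1), gm, wm)),
               50)
  v3 <- v2; v3[1, 1, 1] <- NA
  m <- mean_parenchymal_cbf(voxel_grid(v3, 1), gm, wm)
  expect_equal(attr(m, "n_used"), sum(gm | wm) - 1L)
  expect_error(mean_parenchymal_cbf(g, gm & FALSE, wm & FALSE), "empty")
})

test_that("PC and ASL routes agree on matched phantom cohorts", {
  # structural concordance harness: matched truths -> correlation ~ 1
  set.seed(44)
  truths <- runif(8, 30, 60)
  pc_vals <- vapply(truths, function(cbf) {
    flow <- cbf * 1.06 * 1200 / 100
    f <- flow / 4
    normalized_cbf(c(LICA = f, RICA = f, LVA = f, RVA = f), 700,
                   500)$normalized_cbf_ml_100g_min
  }, numeric(1))
  asl_vals <- vapply(truths, function(cbf) {
    ph <- gen_asl_phantom(voxel_grid(array(cbf, c(4, 4, 4)), 3.5))
    out <- asl_cbf(ph$control, ph$label, ph$m0)
    as.numeric(mean_parenchymal_cbf(out, array(TRUE, c(4, 4, 4)),
                                    array(FALSE, c(4, 4, 4))))
  }, numeric(1))
  expect_gt(cor(pc_vals, asl_vals), 0.999)
})
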