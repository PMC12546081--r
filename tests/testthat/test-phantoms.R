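test_that("rasterize_tube produces a consistent, reproducible tube", {
  cv <- gen_curve(curve_spec("straight", length_mm = 40))
  ph <- rasterize_tube(cv, tube_radius_mm = 3, spacing_mm = 1)
  # noiseless: binarizing at half intensity reproduces the tube voxel set
  expect_identical(ph$volume$values >= 50, ph$tube_mask)
  # truth centerline lies inside the rasterized tube
  idx <- round(physical_to_index(ph$volume, ph$truth_centerline$points))
  expect_true(all(ph$tube_mask[idx]))
  # same seed -> bit-identical; different seed -> different noise
  a <- rasterize_tube(cv, 3, 1, noise_sigma = 5, seed = 99)
  b <- rasterize_tube(cv, 3, 1, noise_sigma = 5, seed = 99)
  c <- rasterize_tube(cv, 3, 1, noise_sigma = 5, seed = 100)
  expect_identical(a$volume$values, b$volume$values)
  expect_false(identical(a$volume$values, c$volume$values))
  # per-slice lumen area within 15% of pi r^2 away from the end caps
  zs <- 10:30
  areas <- vapply(zs, function(k) sum(ph$tube_mask[, , k]), numeric(1))
  expect_true(all(abs(areas - pi * 9) / (pi * 9) < 0.15))
})

test_that("rasterize_tube validates geometry", {
  cv <- gen_curve(curve_spec("straight", length_mm = 40))
  expect_error(rasterize_tube(cv, tube_radius_mm = 1.5, spacing_mm = 1),
               "resolvable")
  expect_error(
    rasterize_tube(cv, 3, 1, dim = c(10L, 10L, 10L),
                   origin_mm = c(-5, -5, 0)),
    "exits")
})

test_that("PC phantom stores a self-consistent discrete flow truth", {
  ph <- gen_pc_phantom(3, 10, "plug", pixel_size_mm = 0.45)
  # analytic 100 mm/s * pi * 9 mm^2 * 60/1000 = 169.65 ml/min
  expect_equal(ph$truth_flow_ml_min, 169.646, tolerance = 0.05)
  expect_equal(flow_from_slice(ph), ph$truth_flow_ml_min, tolerance = 1e-12)
  pb <- gen_pc_phantom(3, 10, "parabolic", pixel_size_mm = 0.45)
  expect_equal(pb$truth_flow_ml_min / ph$truth_flow_ml_min, 0.5,
               tolerance = 0.02)
  z <- gen_pc_phantom(3, 0, "plug")
  expect_equal(z$truth_flow_ml_min, 0)
  expect_equal(max(abs(z$phase_rad)), 0)
  expect_error(gen_pc_phantom(3, 60, "plug", venc_cm_s = 60), "aliasing")
})

test_that("ASL phantom inverts the consensus quantification exactly", {
  set.seed(21)
  cbf_truth <- array(runif(6 * 6 * 6, 20, 80), c(6, 6, 6))
  ph <- gen_asl_phantom(voxel_grid(cbf_truth, 3.5))
  out <- asl_cbf(ph$control, ph$label, ph$m0)
  expect_lt(max(abs(out$cbf_map$values - cbf_truth) / cbf_truth), 1e-10)
  # zero perfusion -> zero difference signal
  z <- gen_asl_phantom(voxel_grid(array(0, c(3, 3, 3)), 3.5))
  expect_equal(z$control$values, z$label$values)
  # CBF scales inversely with labeling efficiency in the closed form
  ph2 <- gen_asl_phantom(voxel_grid(array(50, c(3, 3, 3)), 3.5),
                         asl_params(alpha = 2 * 0.85))
  out2 <- asl_cbf(ph2$control, ph2$label, ph2$m0, asl_params())
  expect_equal(unname(out2$cbf_map$values[1, 1, 1]), 100, tolerance = 1e-10)
  expect_error(gen_asl_phantom(voxel_grid(array(-1, c(2, 2, 2)), 1)),
               "non-negative")
})

test_that("lesion scenes realize requested offsets and labels", {
  sc <- gen_lesion_scene(c(5, 20), spacing_mm = 1)
  expect_equal(sc$truth$truth_label, c("PVWM", "DWM"))
  expect_equal(sc$truth$truth_min_distance_mm, c(5, 20))
  # masks disjoint
  expect_equal(sum(sc$lesion_mask$values * sc$ventricle_mask$values), 0)
  # boundary: 13 mm exactly is deep white matter ("13 mm or further")
  sb <- gen_lesion_scene(c(13), spacing_mm = c(1, 1, 0.5))
  expect_equal(sb$truth$truth_label, "DWM")
  # empty scene
  se <- gen_lesion_scene(numeric(0))
  expect_equal(nrow(se$truth), 0)
  expect_equal(sum(se$lesion_mask$values), 0)
  expect_error(gen_lesion_scene(c(0.5), spacing_mm = 1), "overlap")
})

test_that("gen_cohort is seeded, scaled and plants the stated structure", {
  spec <- cohort_spec(n_subjects = 600, seed = 17)
  tab <- gen_cohort(spec)
  expect_identical(tab, gen_cohort(spec))
  expect_equal(nrow(tab), 600)
  expect_equal(mean(tab$age), 73.1, tolerance = 1)
  expect_equal(sd(tab$age), 5.5, tolerance = 0.8)
  expect_equal(mean(tab$sex == "F"), 42 / 75, tolerance = 0.08)
  # lesion volumes partition exactly
  expect_equal(tab$lesion_pvwm_cm3 + tab$lesion_dwm_cm3,
               tab$lesion_total_cm3)
  # severe group has the planted ICM shift
  shift <- mean(tab$icm_index[tab$group == "severe"]) -
           mean(tab$icm_index[tab$group == "mild"])
  expect_equal(shift, 2.25, tolerance = 0.4)
  # null partial correlation spec
  tn <- gen_cohort(cohort_spec(n_subjects = 2000,
                               target_partial_r_icm_cbf = 0, seed = 2))
  r0 <- partial_correlation(tn$icm_index, tn$normalized_cbf,
                            data.frame(age = tn$age,
                                       sex = as.numeric(tn$sex == "F")))
  expect_lt(abs(r0$statistic), 2 / sqrt(2000))
  expect_error(cohort_spec(n_subjects = 4), "n_subjects")
  expect_error(cohort_spec(target_partial_r_icm_cbf = 1.2), "partial")
})
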