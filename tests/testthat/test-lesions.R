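test_that("lesion_components labels with deterministic ids", {
  m <- array(0, c(10, 10, 10))
  m[2:3, 2:3, 2:3] <- 1
  m[7:8, 7:8, 7:8] <- 1
  comp <- lesion_components(voxel_grid(m, 1))
  expect_equal(nrow(comp$table), 2L)
  expect_equal(comp$table$voxel_count, c(8L, 8L))
  expect_equal(nrow(lesion_components(voxel_grid(m * 0, 1))$table), 0L)
  # edge-touching voxels form one component under 18-connectivity
  e <- array(0, c(5, 5, 5)); e[2, 2, 2] <- 1; e[3, 3, 2] <- 1
  expect_equal(nrow(lesion_components(voxel_grid(e, 1))$table), 1L)
  # probability maps are binarized at 0.5
  p <- array(0, c(5, 5, 5)); p[2, 2, 2] <- 0.6; p[4, 4, 4] <- 0.4
  cp <- lesion_components(voxel_grid(p, 1))
  expect_equal(sum(cp$table$voxel_count), 1L)
})

test_that("distance_to_ventricle honors slab geometry and anisotropy", {
  sc <- gen_lesion_scene(c(5, 20), spacing_mm = 1)
  comp <- distance_to_ventricle(lesion_components(sc$lesion_mask),
                                sc$ventricle_mask)
  expect_equal(comp$table$min_distance_mm, c(5, 20), tolerance = 1e-9)
  # anisotropic z spacing scales the vertical distance
  sc3 <- gen_lesion_scene(c(15), spacing_mm = c(1, 1, 3))
  comp3 <- distance_to_ventricle(lesion_components(sc3$lesion_mask),
                                 sc3$ventricle_mask)
  expect_equal(comp3$table$min_distance_mm, 15, tolerance = 1e-9)
  # a lesion voxel adjacent to the ventricle is within one voxel diagonal
  scn <- gen_lesion_scene(c(1), spacing_mm = 1)
  compn <- distance_to_ventricle(lesion_components(scn$lesion_mask),
                                 scn$ventricle_mask)
  expect_lte(compn$table$min_distance_mm, sqrt(3))
  expect_error(distance_to_ventricle(lesion_components(sc$lesion_mask),
                                     sc$lesion_mask$values * 0), "empty")
})

test_that("the 13-mm rule classifies with an inclusive DWM boundary", {
  sc <- gen_lesion_scene(c(5, 12.9, 13, 20), spacing_mm = c(1, 1, 0.1))
  comp <- classify_pv_dwm(
    distance_to_ventricle(lesion_components(sc$lesion_mask),
                          sc$ventricle_mask))
  expect_equal(comp$table$label, c("PVWM", "PVWM", "DWM", "DWM"))
  expect_equal(comp$table$label, sc$truth$truth_label)
  expect_error(classify_pv_dwm(lesion_components(sc$lesion_mask)),
               "distance_to_ventricle")
})

test_that("lesion volumes partition exactly into PVWM + DWM", {
  sc <- gen_lesion_scene(c(6, 25), component_size_vox = c(3L, 4L),
                         spacing_mm = c(0.5, 0.5, 0.5))
  comp <- classify_pv_dwm(
    distance_to_ventricle(lesion_components(sc$lesion_mask),
                          sc$ventricle_mask))
  vols <- lesion_volumes(comp)
  expect_identical(vols$pvwm_cm3 + vols$dwm_cm3, vols$total_cm3)
  expect_equal(vols$total_cm3, (27 + 64) * 0.125 / 1000)
  expect_equal(vols$pvwm_cm3, 27 * 0.125 / 1000)
  # 100 voxels x 1 mm^3 = 0.1 cm^3
  m <- array(0, c(10, 10, 10)); m[1:4, 1:5, 1:5] <- 1
  c2 <- lesion_components(voxel_grid(m, 1))
  c2$table$min_distance_mm <- 20
  c2 <- classify_pv_dwm(c2)
  expect_equal(lesion_volumes(c2, 1)$total_cm3, 0.1)
  # per-voxel variant splits counts but conserves the total
  sc2 <- gen_lesion_scene(c(11), component_size_vox = 5L, spacing_mm = 1)
  cpv <- classify_pv_dwm(
    distance_to_ventricle(lesion_components(sc2$lesion_mask),
                          sc2$ventricle_mask),
    per_voxel = TRUE, ventricle_mask = sc2$ventricle_mask)
  expect_equal(cpv$table$pvwm_voxels + cpv$table$dwm_voxels,
               cpv$table$voxel_count)
  expect_gt(cpv$table$dwm_voxels, 0) # top layers of the box cross 13 mm
})
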