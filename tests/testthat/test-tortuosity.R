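test_that("count_turns matches analytic inflection counts", {
  expect_equal(count_turns(line_centerline(60, n = 121L)), 0L)
  # half circle: constant curvature, no inflection
  expect_equal(count_turns(resample_centerline(arc_centerline(30, pi), 0.5)),
               0L)
  # planar sinusoids sampled directly from the analytic curve
  for (k in 1:4) {
    cv <- gen_curve(curve_spec("planar_sinusoid", length_mm = 100,
                               amplitude_mm = 10, periods = k,
                               sample_step_mm = 0.5))
    cl <- centerline(cv$points)
    expect_equal(count_turns(cl), 2L * k - 1L,
                 info = sprintf("periods = %d", k))
  }
  expect_error(count_turns(line_centerline(10, n = 3L)), "5 points")
})

test_that("icm multiplies turns by the path/chord ratio", {
  st <- line_centerline(50, n = 101L)
  m <- icm(st)
  expect_equal(m$length_ratio, 1, tolerance = 1e-12)
  expect_equal(m$icm, 0)
  expect_equal(icm(st, convention = "bullitt_plus_one")$icm, 1,
               tolerance = 1e-12)
  # semicircle ratio pi/2
  semi <- resample_centerline(arc_centerline(30, pi), 0.25)
  ms <- icm(semi)
  expect_equal(ms$length_ratio, pi / 2, tolerance = 1e-4)
  expect_equal(ms$n_turns, 0L)
  # sinusoid: icm = turns x numerically integrated length ratio
  cv <- gen_curve(curve_spec("planar_sinusoid", length_mm = 100,
                             amplitude_mm = 10, periods = 2,
                             sample_step_mm = 0.25))
  R <- sinusoid_arc_length(100, 10, 2) / 100
  mi <- icm(centerline(cv$points))
  expect_equal(mi$icm, 3 * R, tolerance = 1e-3)
  # degenerate: closed loop has zero chord
  th <- seq(0, 2 * pi, length.out = 200)
  loop <- centerline(cbind(cos(th), sin(th), 0))
  expect_error(icm(loop), "degenerate")
})

test_that("length ratio is >= 1 with equality only for collinear points", {
  set.seed(9)
  for (i in 1:20) {
    pts <- matrix(rnorm(30), ncol = 3)
    cl <- centerline(pts)
    expect_gte(path_length(cl) - chord_length(cl), -1e-9)
  }
  expect_equal(path_length(line_centerline(5)) /
                 chord_length(line_centerline(5)), 1, tolerance = 1e-9)
})

test_that("icm_index applies the 0.8/0.2 supply weights exactly", {
  expect_equal(icm_index(5, 10), 6)
  expect_equal(icm_index(3.3, 3.3), 3.3)
  expect_equal(icm_index(0, 0), 0)
  # linear and permutation-asymmetric
  expect_equal(icm_index(2 * 5, 2 * 10), 2 * icm_index(5, 10))
  expect_false(isTRUE(all.equal(icm_index(5, 10), icm_index(10, 5))))
  expect_error(icm_index(-1, 2), "non-negative")
})

test_that("ica_angle measures the bifurcation angle", {
  cca <- line_centerline(20, dir = c(0, 0, 1))
  expect_equal(ica_angle(cca, line_centerline(20, dir = c(0, 0, 1))), 0,
               tolerance = 1e-6)
  ica45 <- line_centerline(20, dir = c(1, 0, 1))
  expect_equal(ica_angle(cca, ica45), 45, tolerance = 1e-6)
  expect_equal(ica_angle(cca, line_centerline(20, dir = c(1, 0, 0))), 90,
               tolerance = 1e-6)
  expect_error(ica_angle(cca, line_centerline(5, dir = c(1, 0, 0))),
               "window")
})

test_that("subject_tortuosity averages sides then weights territories", {
  st <- subject_tortuosity(6, 8, 3, 5, ica_angle_deg = 50)
  expect_equal(st$ica_icm, 7)
  expect_equal(st$va_icm, 4)
  expect_equal(st$icm_index, 0.8 * 7 + 0.2 * 4)
  expect_error(subject_tortuosity(1, 1, 1, 1, ica_angle_deg = 190), "0, 180")
})
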