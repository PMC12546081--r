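test_that("normality gate is calibrated and powered", {
  set.seed(101)
  level <- mean(replicate(150, normality_gate(rnorm(200))$verdict) ==
                  "normal")
  expect_gte(level, 0.90) # nominal 95% acceptance of a true normal
  power <- mean(replicate(60, normality_gate(rexp(200))$verdict) ==
                  "non_normal")
  expect_gte(power, 0.95)
  const <- normality_gate(rep(3, 20))
  expect_equal(const$verdict, "non_normal")
  expect_equal(const$note, "constant input")
  expect_error(normality_gate(1:3), "n >= 5")
  # deterministic: same data, same p
  x <- rnorm(50)
  expect_identical(normality_gate(x)$p_value, normality_gate(x)$p_value)
})

test_that("compare_groups dispatches on the gate and detects shifts", {
  set.seed(110)
  x <- rnorm(50); y <- rnorm(50) + 2
  res <- compare_groups(c(x, y), rep(c("a", "b"), each = 50))
  expect_equal(res$test_name, "welch_t")
  expect_lt(res$p_value, 0.001)
  # identical groups: p ~ 1
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 50))
  expect_gt(same$p_value, 0.99)
  # non-normal data routes to Mann-Whitney
  e1 <- rexp(100); e2 <- rexp(100)
  resu <- compare_groups(c(e1, e2), rep(c("a", "b"), each = 100))
  expect_equal(resu$test_name, "mann_whitney_u")
  # U statistic equals brute-force pairwise counting at tiny n (forced
  # onto the U branch via exponential-shaped groups is not guaranteed at
  # n = 8, so count directly against the returned statistic)
  xs <- c(1.2, 3.4, 0.5, 7.8); ys <- c(2.2, 0.1, 5.5, 9.9)
  wt <- suppressWarnings(stats::wilcox.test(xs, ys, exact = FALSE))
  brute <- sum(outer(xs, ys, `>`)) + 0.5 * sum(outer(xs, ys, `==`))
  expect_equal(unname(wt$statistic), brute)
  expect_error(compare_groups(x, rep("a", 50)), "2 levels")
  expect_error(compare_groups(c(x[1:4], y[1:2]),
                              c("a", "a", "a", "a", "b", "b")), "n >= 3")
})

test_that("chi_square_2x2 matches the direct Pearson formula", {
  res <- chi_square_2x2(matrix(c(17, 25, 22, 11), 2, 2))
  expect_equal(res$statistic, 5.0786, tolerance = 1e-4)
  expect_equal(res$p_value, 0.0242, tolerance = 1e-3)
  expect_equal(chi_square_2x2(matrix(10, 2, 2))$statistic, 0)
  # random tables against sum((O-E)^2/E)
  set.seed(103)
  for (i in 1:10) {
    tb <- matrix(rpois(4, 20) + 1, 2, 2)
    E <- outer(rowSums(tb), colSums(tb)) / sum(tb)
    expect_equal(chi_square_2x2(tb)$statistic, sum((tb - E)^2 / E),
                 tolerance = 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margins")
  expect_error(chi_square_2x2(matrix(c(1.5, 2, 3, 4), 2, 2)), "integers")
})

test_that("bh_fdr reproduces the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  # properties: order preserved, adjusted >= raw, monotone in p-order
  set.seed(104)
  p <- runif(20)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  # NAs preserved in place and excluded from the family
  pa <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(pa[2]))
  expect_equal(pa[c(1, 3)], bh_fdr(c(0.01, 0.04)))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("partial_correlation removes covariates and recovers plants", {
  set.seed(105)
  x <- rnorm(200); y <- 0.5 * x + rnorm(200)
  plain <- partial_correlation(x, y)
  expect_equal(plain$statistic, cor(x, y), tolerance = 1e-12)
  # both variables purely driven by the covariate -> r ~ 0
  z <- rnorm(500)
  pc <- partial_correlation(2 * z + rnorm(500, 0, 1e-8),
                            -3 * z + rnorm(500, 0, 1e-8),
                            data.frame(z = z))
  expect_lt(abs(pc$statistic), 0.05)
  # invariance to affine covariate rescaling
  cov1 <- data.frame(a = z)
  cov2 <- data.frame(a = 100 * z - 7)
  x2 <- rnorm(500) + z; y2 <- rnorm(500) - z
  expect_equal(partial_correlation(x2, y2, cov1)$statistic,
               partial_correlation(x2, y2, cov2)$statistic,
               tolerance = 1e-12)
  # planted cohort correlation recovered at large n
  tab <- gen_cohort(cohort_spec(n_subjects = 5000, seed = 106))
  pr <- partial_correlation(tab$icm_index, tab$normalized_cbf,
                            data.frame(age = tab$age,
                                       sex = as.numeric(tab$sex == "F")))
  expect_equal(pr$statistic, -0.35, tolerance = 0.03)
  expect_error(partial_correlation(x[1:4], y[1:4], data.frame(z = z[1:4])),
               "covariates")
  expect_error(partial_correlation(x2, y2,
                                   data.frame(a = z, b = 2 * z)),
               "rank")
})

test_that("wmh_regression recovers exact and planted coefficients", {
  tab <- gen_cohort(cohort_spec(n_subjects = 120, seed = 107))
  # noiseless outcome built from the design -> coefficients exact
  tab$lesion_total_cm3 <- 2 + 0.4 * tab$age - 1.5 * (tab$sex == "M") +
    0.02 * tab$systolic_bp - 0.03 * tab$diastolic_bp + 0.1 * tab$bmi +
    1.2 * tab$icm_index + 0.05 * tab$ica_angle_deg
  fit <- suppressWarnings(wmh_regression(tab, "total")) # exact fit
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est["icm_index"]), 1.2, tolerance = 1e-8)
  expect_equal(unname(est["age"]), 0.4, tolerance = 1e-8)
  expect_equal(unname(est["sex_m"]), -1.5, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_equal(fit$df1, 7)
  expect_equal(fit$n_used, sum(complete.cases(
    tab[, c("systolic_bp", "diastolic_bp")])))
  # standardized coefficient of a z-scored predictor
  expect_true(all(is.finite(fit$coefficients$std_estimate)))
  expect_error(wmh_regression(tab[1:10, ], "total"), "15")
  tabc <- tab; tabc$ica_angle_deg <- tabc$icm_index * 2
  expect_error(wmh_regression(tabc, "total"), "collinear")
})

test_that("wmh_regression CIs cover the planted slope and null p is flat", {
  hits <- 0L
  for (i in 1:60) {
    tb <- gen_cohort(cohort_spec(n_subjects = 300, seed = 5000 + i))
    fit <- wmh_regression(tb, "total")
    ci <- fit$coefficients[fit$coefficients$term == "icm_index", ]
    hits <- hits + (ci$ci_lo <= 1.2 && 1.2 <= ci$ci_hi)
  }
  expect_gte(hits / 60, 0.90)
  # pure-noise outcome: nominal rejection near 5%
  set.seed(108)
  rej <- mean(vapply(1:100, function(i) {
    tb <- gen_cohort(cohort_spec(n_subjects = 100, seed = 7000 + i))
    tb$lesion_total_cm3 <- rnorm(nrow(tb))
    wmh_regression(tb, "total")$model_p_value < 0.05
  }, logical(1)))
  expect_lt(rej, 0.15)
})

test_that("sex_slopes reproduces exactly linear per-sex relationships", {
  tab <- gen_cohort(cohort_spec(n_subjects = 80, seed = 109))
  tab$lesion_total_cm3 <- ifelse(tab$sex == "F",
                                 -0.31 * tab$normalized_cbf + 18.67,
                                 -0.16 * tab$normalized_cbf + 8.91)
  sl <- sex_slopes(tab)
  expect_equal(sl$slope[sl$sex == "F"], -0.31, tolerance = 1e-9)
  expect_equal(sl$intercept[sl$sex == "F"], 18.67, tolerance = 1e-9)
  expect_equal(sl$slope[sl$sex == "M"], -0.16, tolerance = 1e-9)
  # closed-form simple-regression oracle cov/var
  f <- tab[tab$sex == "F", ]
  expect_equal(sl$slope[sl$sex == "F"],
               cov(f$normalized_cbf, f$lesion_total_cm3) /
                 var(f$normalized_cbf), tolerance = 1e-9)
  single <- tab[tab$sex == "F", ]
  expect_error(sex_slopes(single), "both sexes")
})
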