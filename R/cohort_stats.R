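#' Normality gate for the group-comparison dispatch
#'
#' One-sample Kolmogorov-Smirnov test of composite normality with the mean
#' and SD estimated from the sample (the Lilliefors variant - the classical
#' KS null distribution is invalid once parameters are estimated). The
#' p-value is obtained from a seeded Monte-Carlo null of the same sample
#' size, which is exact up to simulation noise at any n; the simulation
#' uses an isolated RNG stream so the gate is deterministic and does not
#' disturb the caller's random state. Verdict: `"normal"` iff p >= alpha.
#'
#' @param values numeric sample, n >= 5 after NA removal.
#' @param alpha gate level (default 0.05).
#' @param n_sim Monte-Carlo null size (default 1000).
#' @return list with `verdict` ("normal"/"non_normal"), `statistic`
#'   (Lilliefors D), `p_value`, `n_used`, `note`.
#' @export
normality_gate <- function(values, alpha = 0.05, n_sim = 1000L) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n < 5L) stop_input("normality gate needs n >= 5 (got %d)", n)
  if (stats::sd(x) == 0)
    return(list(verdict = "non_normal", statistic = NA_real_,
                p_value = 0, n_used = n, note = "constant input"))
  D <- lilliefors_D(x)
  Dnull <- with_seed(7208191L + n, {
    vapply(seq_len(n_sim), function(i) lilliefors_D(rnorm(n)), numeric(1))
  })
  p <- (1 + sum(Dnull >= D)) / (n_sim + 1)
  list(verdict = if (p >= alpha) "normal" else "non_normal",
       statistic = D, p_value = p, n_used = n, note = NA_character_)
}

lilliefors_D <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F0 <- stats::pnorm(z)
  max(max(seq_len(n) / n - F0), max(F0 - (seq_len(n) - 1) / n))
}

#' Normality-gated two-group comparison
#'
#' Welch's two-sample t-test (pooled variance available via
#' `var_equal = TRUE`) when both groups pass the normality gate, otherwise
#' the Mann-Whitney U test; always two-tailed. The branch taken is
#' recorded.
#'
#' @param values numeric outcome.
#' @param group_labels two-level factor/vector aligned with `values`.
#' @param var_equal pooled-variance t-test instead of Welch
#'   (default FALSE).
#' @param alpha gate level passed to [normality_gate()].
#' @return object of class `test_result`: `statistic`, `p_value`,
#'   `test_name`, `n_used`, `normality` (per-group verdicts).
#' @export
compare_groups <- function(values, group_labels, var_equal = FALSE,
                           alpha = 0.05) {
  keep <- !is.na(values) & !is.na(group_labels)
  values <- values[keep]
  g <- factor(group_labels[keep])
  if (nlevels(g) != 2L)
    stop_input("group_labels must have exactly 2 levels (got %d)", nlevels(g))
  ns <- table(g)
  if (any(ns < 3L)) stop_input("each group needs n >= 3")
  x <- values[g == levels(g)[1]]
  y <- values[g == levels(g)[2]]
  gate_x <- normality_gate(x, alpha)
  gate_y <- normality_gate(y, alpha)
  both_normal <- gate_x$verdict == "normal" && gate_y$verdict == "normal"
  if (both_normal) {
    tt <- stats::t.test(x, y, var.equal = var_equal)
    res <- test_result(unname(tt$statistic), tt$p.value,
                       if (var_equal) "t" else "welch_t", length(values))
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
    res <- test_result(unname(wt$statistic), wt$p.value, "mann_whitney_u",
                       length(values))
  }
  res$normality <- c(gate_x$verdict, gate_y$verdict)
  res
}

test_result <- function(statistic, p_value, test_name, n_used,
                        p_adjusted = NA_real_) {
  structure(list(statistic = statistic, p_value = p_value,
                 p_adjusted = p_adjusted, test_name = test_name,
                 n_used = n_used),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g%s, n = %d\n", x$test_name,
              x$statistic, x$p_value,
              if (!is.na(x$p_adjusted))
                sprintf(", p_adj = %.4g", x$p_adjusted) else "",
              x$n_used))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Direct Pearson statistic `sum((O - E)^2 / E)` with 1 degree of freedom
#' and no continuity correction (matching the convention that reproduces
#' the published sex-by-severity statistic).
#'
#' @param counts 2x2 matrix of non-negative integer counts with all
#'   margins positive.
#' @return a `test_result` with `statistic` (chi-square) and `p_value`.
#' @export
chi_square_2x2 <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop_input("counts must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("counts must be non-negative integers")
  n <- sum(counts)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0)) stop_input("all margins must be positive")
  E <- outer(rs, cs) / n
  stat <- sum((counts - E)^2 / E)
  test_result(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE),
              "chi_square", n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values `p_(i) * m / i` with monotonicity enforced
#' from the largest p downward, returned in the input order; adjusted
#' values never fall below the raw p-values. NAs are preserved and excluded
#' from the family size.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  if (any(p < 0 | p > 1)) stop_input("p-values must lie in [0, 1]")
  m <- length(p)
  out <- rep(NA_real_, length(p_values))
  if (m) {
    o <- order(p)
    adj <- pmin(1, p[o] * m / seq_len(m))
    adj <- rev(cummin(rev(adj)))
    padj <- numeric(m)
    padj[o] <- adj
    out[ok] <- padj
  }
  out
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` after
#' projection on `[1, covariates]`; with no covariates this reduces to the
#' plain Pearson correlation. The p-value uses the t distribution with
#' `n - k - 2` degrees of freedom (k = number of covariates), two-sided.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (or NULL).
#' @return `test_result` with `statistic` = partial r and fields `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
  }
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 3L) stop_input("need n > #covariates + 3 (n = %d, k = %d)", n, k)
  if (k) {
    Z <- cbind(1, covariates[keep, , drop = FALSE])
    if (qr(Z)$rank < ncol(Z)) stop_input("covariates are rank deficient")
    rx <- stats::lm.fit(Z, x)$residuals
    ry <- stats::lm.fit(Z, y)$residuals
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  r <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  df <- n - k - 2L
  tval <- r * sqrt(df / (1 - r^2))
  res <- test_result(r, 2 * stats::pt(-abs(tval), df), "partial_correlation", n)
  res$df <- df
  res$t <- tval
  res
}

#' Multiple linear regression of WMH lesion volume
#'
#' Ordinary least squares with the fixed design
#' `lesion ~ age + sex + systolic_bp + diastolic_bp + bmi + icm_index +
#' ica_angle_deg` on complete cases, for one of the three lesion outcomes.
#' Reports coefficients with 95% CIs, standardized coefficients (continuous
#' predictors and the outcome z-scored; the sex indicator left as 0/1),
#' R^2, adjusted R^2 and the model F test `F(k, n - k - 1)`.
#'
#' @param table cohort `data.frame` as produced by [gen_cohort()].
#' @param outcome `"total"`, `"PVWM"` or `"DWM"`.
#' @return object of class `wmh_regression`: `coefficients` data frame
#'   (`term`, `estimate`, `ci_lo`, `ci_hi`, `std_estimate`, `p_value`),
#'   `r_squared`, `adj_r_squared`, `f_statistic`, `df1`, `df2`,
#'   `model_p_value`, `n_used`, `outcome`.
#' @export
wmh_regression <- function(table, outcome = c("total", "PVWM", "DWM")) {
  outcome <- match.arg(outcome)
  ycol <- switch(outcome, total = "lesion_total_cm3",
                 PVWM = "lesion_pvwm_cm3", DWM = "lesion_dwm_cm3")
  preds <- c("age", "sex", "systolic_bp", "diastolic_bp", "bmi",
             "icm_index", "ica_angle_deg")
  need <- c(ycol, preds)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_input("table lacks column(s): %s", paste(miss, collapse = ", "))
  d <- table[stats::complete.cases(table[, need]), need]
  n <- nrow(d)
  if (n < 15L) stop_input("need >= 15 complete cases (got %d)", n)
  d$sex_m <- as.numeric(d$sex == "M")
  form <- stats::as.formula(paste(
    ycol, "~ age + sex_m + systolic_bp + diastolic_bp + bmi + icm_index + ica_angle_deg"))
  X <- stats::model.matrix(form, d)
  cond <- kappa(qr.R(qr(scale(X[, -1]))), exact = TRUE)
  if (!is.finite(cond) || cond > 1e8)
    stop_input("design is (near-)collinear: condition number %.3g", cond)
  fit <- stats::lm(form, data = d)
  ci <- stats::confint(fit, level = 0.95)
  sm <- summary(fit)
  # standardized fit: z-score outcome + continuous predictors
  dz <- d
  for (v in c(ycol, "age", "systolic_bp", "diastolic_bp", "bmi",
              "icm_index", "ica_angle_deg"))
    dz[[v]] <- (dz[[v]] - mean(dz[[v]])) / stats::sd(dz[[v]])
  fitz <- stats::lm(form, data = dz)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = data.frame(
      term = rownames(sm$coefficients),
      estimate = sm$coefficients[, 1],
      ci_lo = ci[, 1], ci_hi = ci[, 2],
      std_estimate = coef(fitz),
      p_value = sm$coefficients[, 4],
      row.names = NULL, stringsAsFactors = FALSE),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(fstat[1]), df1 = unname(fstat[2]),
    df2 = unname(fstat[3]),
    model_p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                              lower.tail = FALSE),
    n_used = n, outcome = outcome),
    class = "wmh_regression")
}

#' @export
print.wmh_regression <- function(x, ...) {
  cat(sprintf("<wmh_regression: %s> n = %d, R^2 = %.3f (adj %.3f), F(%d, %d) = %.2f, p = %.4g\n",
              x$outcome, x$n_used, x$r_squared, x$adj_r_squared,
              x$df1, x$df2, x$f_statistic, x$model_p_value))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Per-sex regression of lesion volume on normalized CBF
#'
#' Simple least-squares line `lesion_total_cm3 ~ normalized_cbf` fitted
#' separately within each sex, exposing sex-specific sensitivity of lesion
#' burden to global blood supply.
#'
#' @param table cohort `data.frame` with `sex`, `normalized_cbf`,
#'   `lesion_total_cm3`.
#' @return data frame with one row per sex: `sex`, `slope`, `intercept`,
#'   `n_used`.
#' @export
sex_slopes <- function(table) {
  keep <- stats::complete.cases(table[, c("sex", "normalized_cbf",
                                          "lesion_total_cm3")])
  d <- table[keep, ]
  sexes <- unique(as.character(d$sex))
  if (length(sexes) < 2L) stop_input("both sexes must be present")
  do.call(rbind, lapply(sort(sexes), function(s) {
    ds <- d[d$sex == s, ]
    if (nrow(ds) < 5L) stop_input("need n >= 5 per sex (sex %s: %d)", s, nrow(ds))
    fit <- stats::lm(lesion_total_cm3 ~ normalized_cbf, data = ds)
    data.frame(sex = s, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]), n_used = nrow(ds),
               stringsAsFactors = FALSE)
  }))
}
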