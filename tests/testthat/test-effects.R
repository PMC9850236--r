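# Shared basis for the effects tests: knots resolved from a fixed sample.
eff_spec <- local({
  set.seed(13)
  crossbasis_spec(rnorm(400, 1.2, 4.3))
})

test_that("cumulative contrast is zero at equal temps and antisymmetric", {
  expect_lt(max(abs(cumulative_contrast(eff_spec, 3, 3))), 1e-15)
  a <- cumulative_contrast(eff_spec, -8, 5)
  expect_lt(max(abs(a + cumulative_contrast(eff_spec, 5, -8))), 1e-12)
})

test_that("cumulative contrast equals the constant-history crossbasis row", {
  # a(x1, x0)' beta must equal the difference of crossbasis rows built from
  # constant series at x1 and at x0 (direct-summation oracle)
  for (pair in list(c(-8, 2), c(-4.7, 6.1), c(0, 10))) {
    row_of <- function(x) {
      build_crossbasis(rep(x, 20), eff_spec)[20, ]
    }
    a <- cumulative_contrast(eff_spec, pair[1], pair[2])
    expect_lt(max(abs(a - unname(row_of(pair[1]) - row_of(pair[2])))), 1e-12)
  }
})

test_that("null coefficients give a flat curve with degenerate CIs", {
  fit0 <- fake_fit(eff_spec, rep(0, 12))
  cv <- cumulative_curve(fit0, ref_temp = 1)
  expect_true(all(cv$or == 1))
  expect_true(all(cv$conf_low == 1 & cv$conf_high == 1))
  ec <- extreme_cold_or(cv)
  expect_equal(c(ec$or, ec$conf_low, ec$conf_high), c(1, 1, 1))
  lr <- lag_response(fit0, x1 = -8, x0 = 1)
  expect_true(all(lr$log_or == 0))
})

test_that("curve CIs bracket the point estimate and zero at the reference", {
  set.seed(14)
  V <- crossprod(matrix(rnorm(24 * 24, 0, 0.01), 24))
  fit <- fake_fit(eff_spec, rnorm(12, 0, 0.05), gamma = rnorm(12, 0, 0.002),
                  V = V)
  grid <- seq(-10, 10, by = 0.5) # contains the reference exactly
  cv <- cumulative_curve(fit, ref_temp = 2, grid = grid)
  expect_true(all(cv$conf_low <= cv$or & cv$or <= cv$conf_high))
  at_ref <- which(cv$temp == 2)
  expect_equal(cv$log_or[at_ref], 0, tolerance = 1e-10)
  expect_equal(cv$se[at_ref], 0, tolerance = 1e-10)
})

test_that("find_mmt returns the grid max under monotone decline and the
           vertex of a calibrated minimum", {
  # monotone: a pure cold-limb truth decreasing in risk with warmth
  s <- calibrate_surface(eff_spec,
                         true_surface_spec(true_mmt = 8, warm_rise = 0))
  fit <- fake_fit(eff_spec, unname(s$beta_star))
  grid <- seq(eff_spec$temp_pctl[["p1"]], eff_spec$temp_range[2], by = 0.1)
  mmt_flat <- find_mmt(fit, grid = grid)
  # curve minimises at/after the calibrated minimum; with warm_rise 0 the
  # warm tail is flat so ties resolve toward the warmest grid point
  expect_gte(mmt_flat, s$true_mmt - 0.1)

  s2 <- calibrate_surface(eff_spec, true_surface_spec(true_mmt = 6))
  fit2 <- fake_fit(eff_spec, unname(s2$beta_star))
  expect_lt(abs(find_mmt(fit2, grid = grid) - s2$true_mmt), 0.1 + 1e-9)

  # reference invariance
  cv_a <- cumulative_curve(fit2, ref_temp = grid[1], grid = grid)
  cv_b <- cumulative_curve(fit2, ref_temp = grid[length(grid)], grid = grid)
  expect_equal(find_mmt(cv_a), find_mmt(cv_b))
})

test_that("modified curves obey the interaction algebra", {
  set.seed(15)
  beta <- rnorm(12, 0, 0.05)
  gamma <- rnorm(12, 0, 0.003)
  V <- crossprod(matrix(rnorm(24 * 24, 0, 0.005), 24))
  fit <- fake_fit(eff_spec, beta, gamma = gamma, V = V)
  a <- cumulative_contrast(eff_spec, -8, 2)
  grid <- seq(-10, 10, by = 0.5) # contains -8 and the reference exactly
  for (p in c(35, 52, 70)) {
    cv <- cumulative_curve(fit, ref_temp = 2, grid = grid, pm_level = p)
    direct <- exp(sum(a * beta) + p * sum(a * gamma))
    got <- extreme_cold_or(cv, at = -8)$or
    expect_equal(got, direct, tolerance = 1e-12)
  }
  # OR ratio across levels depends only on gamma
  or_at <- function(p) extreme_cold_or(
    cumulative_curve(fit, ref_temp = 2, grid = grid, pm_level = p),
    at = -8)$or
  expect_equal(or_at(70) / or_at(35), exp((70 - 35) * sum(a * gamma)),
               tolerance = 1e-10)

  # gamma = 0: identical curves at every level
  fit0 <- fake_fit(eff_spec, beta, gamma = rep(0, 12))
  cv1 <- cumulative_curve(fit0, ref_temp = 2, grid = grid, pm_level = 30)
  cv2 <- cumulative_curve(fit0, ref_temp = 2, grid = grid, pm_level = 90)
  expect_equal(cv1$log_or, cv2$log_or, tolerance = 1e-12)
})

test_that("percent change per 10 inverts its defining formula exactly", {
  a <- cumulative_contrast(eff_spec, -8, 2)
  # gamma proportional to a, scaled so 10 * a'gamma = log(1.076)
  gamma <- a * (log(1.076) / 10) / sum(a * a)
  fit <- fake_fit(eff_spec, rep(0, 12), gamma = gamma)
  out <- pct_change_per_10(fit, x1 = -8, x0 = 2)
  expect_equal(out$pct, 7.6, tolerance = 1e-9)

  fit0 <- fake_fit(eff_spec, rep(0, 12))
  out0 <- pct_change_per_10(fit0, x1 = -8, x0 = 2)
  expect_equal(c(out0$pct, out0$conf_low, out0$conf_high), c(0, 0, 0))
})

test_that("pct-per-10 reproduces modified-OR ratios exactly", {
  set.seed(16)
  fit <- fake_fit(eff_spec, rnorm(12, 0, 0.05),
                  gamma = rnorm(12, 0, 0.002))
  p1 <- 38; p2 <- 71
  grid <- seq(-10, 10, by = 0.5)
  pct <- pct_change_per_10(fit, x1 = -8, x0 = 2)$pct
  or1 <- extreme_cold_or(cumulative_curve(fit, 2, grid = grid,
                                          pm_level = p1), at = -8)$or
  or2 <- extreme_cold_or(cumulative_curve(fit, 2, grid = grid,
                                          pm_level = p2), at = -8)$or
  expect_equal(or2 / or1, (1 + pct / 100)^((p2 - p1) / 10),
               tolerance = 1e-10)
})

test_that("lag-specific effects sum to the cumulative effect", {
  set.seed(17)
  fit <- fake_fit(eff_spec, rnorm(12, 0, 0.05),
                  gamma = rnorm(12, 0, 0.002),
                  V = crossprod(matrix(rnorm(24 * 24, 0, 0.004), 24)))
  lr <- lag_response(fit, x1 = -8, x0 = 2)
  a <- cumulative_contrast(eff_spec, -8, 2)
  expect_equal(sum(lr$log_or), sum(a * fit$beta[fit$col_groups$cb]),
               tolerance = 1e-10)
  lrp <- lag_response(fit, x1 = -8, x0 = 2, pm_level = 52)
  eff <- fit$beta[fit$col_groups$cb] + 52 * fit$beta[fit$col_groups$interaction]
  expect_equal(sum(lrp$log_or), sum(a * eff), tolerance = 1e-10)
})

test_that("a front-loaded truth has its largest lag effect at lag 0", {
  s <- calibrate_surface(eff_spec, true_surface_spec(true_mmt = 6))
  fit <- fake_fit(eff_spec, unname(s$beta_star))
  lr <- lag_response(fit, x1 = eff_spec$temp_pctl[["p1"]], x0 = s$true_mmt)
  expect_equal(which.max(abs(lr$log_or)), 1L)
  expect_gt(lr$log_or[1], 0)
})
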