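test_that("degenerate noise gives constant series", {
  cfg <- sim_config(n_seasons = 1L,
                    temp = list(mean = 2, sd = 0, ar = 0),
                    rh = list(mean = 60, sd = 0),
                    pm1 = list(log_median = log(50), log_sd = 0,
                               coupling = 0),
                    pm25 = list(log_median = log(80), log_sd = 0,
                                coupling = 0))
  e <- simulate_exposures(cfg)
  expect_true(all(e$temp_c == 2))
  expect_true(all(e$rh_pct == 60))
  expect_equal(unique(e$pm1), 50, tolerance = 1e-12)
  expect_equal(unique(e$pm25), 80, tolerance = 1e-12)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(baseline_rate = 0),
               class = "coldmod_config_error")
  expect_error(sim_config(temp = list(mean = 0, sd = -1, ar = 0)),
               class = "coldmod_config_error")
  expect_error(sim_config(temp = list(mean = 0, sd = 1, ar = 1.2)),
               class = "coldmod_config_error")
  expect_error(
    sim_config(pm1 = list(log_median = 1, log_sd = 0.2, coupling = 0.1)),
    class = "coldmod_config_error"
  )
})

test_that("the same seed reproduces the study exactly", {
  a <- simulate_study(sim_config(n_seasons = 1L, baseline_rate = 20,
                                 seed = 9))
  b <- simulate_study(sim_config(n_seasons = 1L, baseline_rate = 20,
                                 seed = 9))
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$deaths, b$deaths)
  c <- simulate_study(sim_config(n_seasons = 1L, baseline_rate = 20,
                                 seed = 10))
  expect_false(identical(a$deaths, c$deaths))
})

test_that("seasons cover the configured months plus lead-in only", {
  cfg <- sim_config(n_seasons = 2L, lead_in_days = 15L)
  w <- simulate_weather(cfg)
  ins <- w[w$in_season, ]
  expect_setequal(as.integer(format(ins$date, "%m")), c(11L, 12L, 1L, 2L))
  expect_equal(sum(!w$in_season), 2L * 15L)
  # lead-in immediately precedes each season block
  first_season_day <- min(ins$date)
  expect_true((first_season_day - 1) %in% w$date[!w$in_season])
})

test_that("marginal quantiles match the configured climatology", {
  # ~10,000 in-season days
  cfg <- sim_config(n_seasons = 84L, seed = 123)
  e <- simulate_exposures(cfg)
  ins <- e[e$in_season, ]
  expect_gt(nrow(ins), 9900)
  expect_lt(abs(median(ins$temp_c) - 1.17), 0.5)
  expect_lt(abs(median(ins$pm25) - 81.34) / 81.34, 0.05)
  expect_lt(abs(median(ins$pm1) - 51.78) / 51.78, 0.05)
  # interquartile ranges near the configured spread
  expect_lt(abs(IQR(ins$temp_c) - (4.37 - (-1.49))), 0.6)
  # negative temperature coupling: colder days more polluted
  expect_lt(cor(ins$temp_c, log(ins$pm1)), 0)
  expect_lt(cor(ins$temp_c, log(ins$pm25)), 0)
  # the two fractions are strongly correlated
  expect_gt(cor(log(ins$pm1), log(ins$pm25)), 0.5)
  expect_true(all(ins$rh_pct >= 0 & ins$rh_pct <= 100))
})

test_that("surface calibration hits its targets in closed form", {
  set.seed(33)
  spec <- crossbasis_spec(rnorm(500, 1.2, 4.3))
  p1 <- spec$temp_pctl[["p1"]]

  s <- calibrate_surface(spec, true_surface_spec(target_or_p1 = 1.83,
                                                 true_mmt = 8))
  a <- cumulative_contrast(spec, p1, s$true_mmt)
  expect_equal(exp(sum(a * s$beta_star)), 1.83, tolerance = 1e-8)
  expect_equal(s$gamma_star, 0 * s$gamma_star) # pct 0 -> zero interaction

  s1 <- calibrate_surface(spec, true_surface_spec(target_or_p1 = 1,
                                                  true_mmt = 8))
  expect_equal(sum(cumulative_contrast(spec, p1, s1$true_mmt) *
                     s1$beta_star), 0, tolerance = 1e-10)

  s2 <- calibrate_surface(spec,
                          true_surface_spec(target_or_p1 = 1.83,
                                            pct_per_10 = 7.6, true_mmt = 8))
  a2 <- cumulative_contrast(spec, p1, s2$true_mmt)
  expect_equal(100 * (exp(10 * sum(a2 * s2$gamma_star)) - 1), 7.6,
               tolerance = 1e-8)

  # paired-OR mode pins both centering levels
  s3 <- calibrate_surface(spec,
                          true_surface_spec(or_low = 1.60, or_high = 2.20,
                                            true_mmt = 8),
                          pm_low = 35, pm_high = 75)
  a3 <- cumulative_contrast(spec, p1, s3$true_mmt)
  expect_equal(exp(sum(a3 * s3$beta_star) + 35 * sum(a3 * s3$gamma_star)),
               1.60, tolerance = 1e-8)
  expect_equal(exp(sum(a3 * s3$beta_star) + 75 * sum(a3 * s3$gamma_star)),
               2.20, tolerance = 1e-8)

  expect_error(
    calibrate_surface(spec, true_surface_spec(true_mmt = 100)),
    class = "coldmod_calibration_error"
  )
})

test_that("null truth gives Poisson counts at the baseline rate", {
  cfg <- sim_config(n_seasons = 2L, baseline_rate = 50, seed = 17,
                    truth = true_surface_spec(target_or_p1 = 1,
                                              pct_per_10 = 0,
                                              theta_pm = 0))
  sim <- simulate_study(cfg)
  daily <- dplyr::summarise(dplyr::group_by(sim$deaths, .data$date),
                            n = sum(.data$n_deaths))
  n_days <- sum(sim$exposures$in_season)
  mean_rate <- sum(daily$n) / n_days
  # Monte-Carlo tolerance: sd of the mean is sqrt(50 / n_days) ~ 0.46
  expect_lt(abs(mean_rate - 50), 3 * sqrt(50 / n_days))
})

test_that("the generative rate reproduces the target OR empirically", {
  # empirical oracle: two long constant-temperature regimes (P1-history
  # days vs MMT-history days) must show a death-rate ratio near the target
  cfg <- sim_config(seed = 77)
  e <- simulate_exposures(cfg)
  spec <- crossbasis_spec(e$temp_c[e$in_season])
  s <- calibrate_surface(spec, true_surface_spec(target_or_p1 = 1.83,
                                                 true_mmt = 8,
                                                 theta_pm = 0))
  p1 <- spec$temp_pctl[["p1"]]
  n <- 120L
  craft <- tibble::tibble(
    date = seq(as.Date("2013-11-01") - 21, by = "day",
               length.out = 2L * n + 42L),
    region = "R1",
    in_season = TRUE,
    temp_c = c(rep(p1, n + 21L), rep(s$true_mmt, n + 21L)),
    rh_pct = 55, pm1 = 51.78, pm25 = 81.34, ozone = 50
  )
  craft$in_season[1:21] <- FALSE
  cfg2 <- sim_config(baseline_rate = 5000, seed = 78)
  d <- simulate_deaths(cfg2, craft, s)
  daily <- dplyr::summarise(dplyr::group_by(d, .data$date),
                            n = sum(.data$n_deaths), .groups = "drop")
  # discard the transition window where histories mix
  cold_days <- craft$date[22:(n + 21L)]
  warm_days <- craft$date[(n + 43L):(2L * n + 42L)]
  rate_cold <- sum(daily$n[daily$date %in% cold_days]) / n
  rate_warm <- sum(daily$n[daily$date %in% warm_days]) / n
  expect_lt(abs(rate_cold / rate_warm - 1.83), 0.05)
})

test_that("insufficient lead-in raises an informative error", {
  cfg <- sim_config(n_seasons = 1L, lead_in_days = 3L, baseline_rate = 10)
  e <- simulate_exposures(cfg)
  spec <- crossbasis_spec(e$temp_c[e$in_season])
  s <- calibrate_surface(spec, true_surface_spec(true_mmt = 8))
  expect_error(simulate_deaths(cfg, e, s), "lead-in",
               class = "coldmod_data_error")
})

test_that("study files round-trip through CSV", {
  sim <- small_sim(seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_study(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_study(dir)
  expect_equal(back$exposures$temp_c, sim$exposures$temp_c,
               tolerance = 1e-10)
  expect_equal(back$deaths$n_deaths, sim$deaths$n_deaths)
  expect_s3_class(back$deaths$date, "Date")
})

test_that("subgroup labels and shares are plausible", {
  sim <- small_sim(seed = 12, baseline_rate = 200)
  d <- sim$deaths
  expect_setequal(unique(d$sex), c("male", "female"))
  expect_setequal(unique(d$age_group), c("<75", ">=75"))
  expect_true(any(is.na(d$education)))
  tot <- sum(d$n_deaths)
  male <- sum(d$n_deaths[d$sex == "male"]) / tot
  expect_lt(abs(male - 0.5597), 0.02)
})
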