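# Synthetic cold-season study generator: environmental series calibrated to
# the study-region climatology and Poisson mortality under a known
# exposure-lag-response surface, so the whole pipeline is testable by
# parameter recovery.

#' Simulation configuration
#'
#' Study conditions for the synthetic generator. Defaults emulate a
#' cold-season (November-February) series whose temperature and particulate
#' distributions match the study region's reported quantiles: temperature
#' median 1.17 C with interquartile range (-1.49, 4.37) C, PM1 median
#' 51.78 ug/m3, PM2.5 median 81.34 ug/m3. Temperature follows a stationary
#' AR(1) within each season; PM1/PM2.5 are correlated log-normals whose
#' log-mean falls with temperature (colder days are more polluted); relative
#' humidity is truncated normal in [0, 100].
#'
#' @param n_seasons Number of cold seasons (default 6).
#' @param start_year First season's starting calendar year (default 2013).
#' @param season_months Calendar months of the cold season, in season order
#'   (default `c(11, 12, 1, 2)`).
#' @param regions Region identifiers (independent series per region).
#' @param baseline_rate Expected deaths/day at reference conditions
#'   (temperature held at the MMT, pollutant at its median), default 400.
#' @param temp List `mean`, `sd` (marginal), `ar` (AR(1) coefficient in
#'   (-1, 1)).
#' @param rh List `mean`, `sd` (percent, truncated to [0, 100]).
#' @param pm1,pm25 Lists `log_median`, `log_sd` (innovation scale), and
#'   `coupling` (change in log concentration per degree C above the
#'   temperature mean; `<= 0`).
#' @param pm_rho Correlation of the PM1 and PM2.5 log innovations
#'   (default 0.8).
#' @param ozone List `log_median`, `log_sd` for an independent log-normal
#'   ozone series.
#' @param truth A [true_surface_spec()] describing the generative
#'   exposure-lag-response.
#' @param lead_in_days Exposure days generated before each season so that
#'   every in-season day has a complete lag history (default 21).
#' @param seed Integer seed; child streams per component are derived from it
#'   deterministically.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_seasons = 6L, start_year = 2013L,
                       season_months = c(11L, 12L, 1L, 2L),
                       regions = "R1",
                       baseline_rate = 400,
                       temp = list(mean = 1.17, sd = 4.34, ar = 0.65),
                       rh = list(mean = 55, sd = 15),
                       pm1 = list(log_median = log(51.78), log_sd = 0.27,
                                  coupling = -0.03),
                       pm25 = list(log_median = log(81.34), log_sd = 0.486,
                                   coupling = -0.03),
                       pm_rho = 0.8, pm_ar = 0.9,
                       ozone = list(log_median = log(50), log_sd = 0.3),
                       truth = true_surface_spec(),
                       lead_in_days = 21L,
                       seed = 1L) {
  assert_positive(baseline_rate, "baseline_rate")
  if (temp$sd < 0 || rh$sd < 0) {
    abort("standard deviations must be non-negative",
          class = "coldmod_config_error")
  }
  if (abs(temp$ar) >= 1 || abs(pm_ar) >= 1) {
    abort("AR(1) coefficients must lie in (-1, 1)",
          class = "coldmod_config_error")
  }
  for (p in list(pm1, pm25)) {
    if (p$log_sd < 0) abort("PM log-sd must be non-negative",
                            class = "coldmod_config_error")
    if (p$coupling > 0) abort("PM temperature coupling must be <= 0",
                              class = "coldmod_config_error")
  }
  structure(
    list(n_seasons = as.integer(n_seasons), start_year = as.integer(start_year),
         season_months = as.integer(season_months), regions = regions,
         baseline_rate = baseline_rate, temp = temp, rh = rh,
         pm1 = pm1, pm25 = pm25, pm_rho = pm_rho, pm_ar = pm_ar,
         ozone = ozone,
         truth = truth, lead_in_days = as.integer(lead_in_days),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Generative truth specification
#'
#' Targets for [calibrate_surface()]: where the cumulative curve's minimum
#' sits, how large the extreme-cold effect is, and how strongly the chosen
#' pollutant modifies it. Either `pct_per_10` or an `(or_low, or_high)` pair
#' (ORs pinned at the pollutant's 10th and 90th percentile) defines the
#' interaction strength.
#'
#' @param true_mmt Requested minimum mortality temperature, degrees C.
#' @param target_or_p1 Cumulative OR at the 1st temperature percentile vs
#'   the MMT (ignored when `or_low`/`or_high` are given).
#' @param pct_per_10 True percent change in the extreme-cold OR per
#'   10 ug/m3 of `pollutant` (default 0: no modification).
#' @param or_low,or_high Optional ORs pinning the modified extreme-cold
#'   effect at the pollutant's 10th and 90th percentile.
#' @param pollutant Modifying pollutant, `"pm1"` or `"pm25"`.
#' @param theta_pm Linear log-rate coefficient of the pollutant moving
#'   average (default 0.001 per ug/m3).
#' @param subgroup_scale Optional named list scaling the interaction
#'   strength per subgroup level, e.g.
#'   `list(age_group = c("<75" = 0.6, ">=75" = 1.4))`.
#' @param warm_rise Fraction of the cold-side (P1) log-OR that the curve
#'   regains at the observed warm extreme (default 0.5); controls how
#'   pronounced the warm-side upturn past the MMT is.
#' @param mode `"spline"` expresses the truth in the estimator's own
#'   crossbasis family (well-specified recovery); `"quadratic"` uses an
#'   explicit quadratic exposure-lag surface outside that family
#'   (misspecified mode, for robustness exploration only).
#' @return List of class `true_surface_spec`.
#' @export
true_surface_spec <- function(true_mmt = 8, target_or_p1 = 1.83,
                              pct_per_10 = 0,
                              or_low = NULL, or_high = NULL,
                              pollutant = c("pm1", "pm25"),
                              theta_pm = 0.001,
                              subgroup_scale = NULL,
                              warm_rise = 0.5,
                              mode = c("spline", "quadratic")) {
  structure(
    list(true_mmt = true_mmt, target_or_p1 = target_or_p1,
         pct_per_10 = pct_per_10, or_low = or_low, or_high = or_high,
         pollutant = match.arg(pollutant), theta_pm = theta_pm,
         subgroup_scale = subgroup_scale, warm_rise = warm_rise,
         mode = match.arg(mode)),
    class = "true_surface_spec"
  )
}

# Dates of one season block: the season months starting in `year`, preceded
# by `lead_in` days of exposure lead-in.
season_block <- function(year, season_months, lead_in) {
  y <- year
  prev <- season_months[1]
  dates <- as.Date(character(0))
  for (m in season_months) {
    if (m < prev) y <- y + 1L
    first <- as.Date(sprintf("%d-%02d-01", y, m))
    last <- seq(first, by = "1 month", length.out = 2L)[2L] - 1L
    dates <- c(dates, seq(first, last, by = "day"))
    prev <- m
  }
  start <- dates[1]
  tibble(
    date = c(seq(start - lead_in, start - 1L, by = "day"), dates),
    in_season = c(rep(FALSE, lead_in), rep(TRUE, length(dates)))
  )
}

#' Simulate daily weather
#'
#' Temperature follows a stationary AR(1) around the configured mean within
#' each season block (independent across seasons and regions); relative
#' humidity is drawn truncated-normal in [0, 100] by inverse-CDF sampling.
#' Each season block includes `lead_in_days` days before the season so that
#' lagged exposure histories are complete from the first season day.
#'
#' @param config A [sim_config()].
#' @return Tibble `date`, `region`, `in_season`, `temp_c`, `rh_pct`.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "weather"))
  tp <- config$temp
  blocks <- purrr::map(
    seq_len(config$n_seasons) - 1L,
    ~ season_block(config$start_year + .x, config$season_months,
                   config$lead_in_days)
  )
  purrr::map_dfr(config$regions, function(rg) {
    purrr::map_dfr(blocks, function(bl) {
      n <- nrow(bl)
      if (tp$sd == 0) {
        x <- rep(tp$mean, n)
      } else {
        innov_sd <- tp$sd * sqrt(1 - tp$ar^2)
        x <- numeric(n)
        x[1] <- rnorm(1, tp$mean, tp$sd)
        eps <- rnorm(n - 1L, 0, innov_sd)
        for (t in seq_len(n - 1L)) {
          x[t + 1L] <- tp$mean + tp$ar * (x[t] - tp$mean) + eps[t]
        }
      }
      rh <- config$rh
      if (rh$sd == 0) {
        h <- rep(rh$mean, n)
      } else {
        lo <- stats::pnorm(0, rh$mean, rh$sd)
        hi <- stats::pnorm(100, rh$mean, rh$sd)
        h <- stats::qnorm(stats::runif(n, lo, hi), rh$mean, rh$sd)
      }
      dplyr::mutate(bl, region = rg, temp_c = x, rh_pct = h,
                    .after = "date")
    })
  })
}

#' Simulate particulate matter and ozone
#'
#' PM1 and PM2.5 are log-normal with log-median shifted by
#' `coupling * (temp - temp_mean)` (coupling is non-positive, so colder days
#' are more polluted). The log deviations follow a stationary AR(1) within
#' each season block (`pm_ar`; multi-day pollution episodes persist, as
#' winter particulate series do), with marginal scale `log_sd` and
#' contemporaneous innovation correlation `pm_rho` between the two size
#' fractions. Ozone is an independent log-normal. No day-wise PM1 <= PM2.5
#' constraint is imposed: the analysis uses the pollutants in separate model
#' sets.
#'
#' @param config A [sim_config()].
#' @param weather Output of [simulate_weather()].
#' @return `weather` with `pm1`, `pm25`, `ozone` columns appended.
#' @export
simulate_pm <- function(config, weather) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, "pm"))
  n <- nrow(weather)
  rho <- config$pm_rho
  ar <- config$pm_ar
  # season blocks: restart the AR at every gap in the daily sequence or
  # region change
  block <- cumsum(c(TRUE, diff(weather$date) != 1 |
                      weather$region[-1] != weather$region[-n]))
  ar1_marginal <- function(sd_marg) {
    if (sd_marg == 0) return(rep(0, n))
    z <- rnorm(n)
    out <- numeric(n)
    innov <- sqrt(1 - ar^2)
    for (i in seq_len(n)) {
      out[i] <- if (i == 1L || block[i] != block[i - 1L]) z[i] else
        ar * out[i - 1L] + innov * z[i]
    }
    out * sd_marg
  }
  e1 <- ar1_marginal(1)
  e2 <- ar1_marginal(1)
  z3 <- rnorm(n)
  dt <- weather$temp_c - config$temp$mean
  p1 <- config$pm1
  p25 <- config$pm25
  weather$pm1 <- exp(p1$log_median + p1$coupling * dt + p1$log_sd * e1)
  weather$pm25 <- exp(p25$log_median + p25$coupling * dt +
                        p25$log_sd * (rho * e1 + sqrt(1 - rho^2) * e2))
  weather$ozone <- exp(config$ozone$log_median + config$ozone$log_sd * z3)
  weather
}

#' Simulate the exposure series
#'
#' Weather plus pollutants in one call.
#'
#' @param config A [sim_config()].
#' @return Tibble `date`, `region`, `in_season`, `temp_c`, `rh_pct`, `pm1`,
#'   `pm25`, `ozone`.
#' @export
simulate_exposures <- function(config) {
  simulate_pm(config, simulate_weather(config))
}

#' Calibrate the generative exposure-lag-response surface
#'
#' Expresses the truth in the estimator's own crossbasis family so recovery
#' is unbiased: a fixed front-loaded lag shape and a quadratic-in-temperature
#' cumulative shape (minimum at the requested MMT) are projected onto the
#' lag and temperature bases, then scaled so the cumulative contrast at the
#' observed 1st temperature percentile equals `log(target_or_p1)` exactly,
#' and the interaction vector so the same contrast under `gamma_star` equals
#' `log(1 + pct_per_10/100)/10` per unit of pollutant. When an
#' `(or_low, or_high)` pair is supplied (with the pollutant concentrations
#' they are pinned at), both scalings are solved from the pair instead.
#'
#' @param cb_spec A [crossbasis_spec()] resolved from the simulated
#'   in-season temperatures.
#' @param truth A [true_surface_spec()].
#' @param pm_low,pm_high Pollutant concentrations at which `or_low` /
#'   `or_high` are pinned (required in pair mode).
#' @param mmt_tol Maximum accepted distance between the requested MMT and
#'   the argmin of the projected curve (default 0.75 C).
#' @return List of class `true_surface`: `beta_star`, `gamma_star`,
#'   `theta_pm`, `true_mmt` (argmin of the implied curve), `target_or_p1`,
#'   `pct_per_10`, `p1_temp`, `cb_spec`, lag weights and shape vectors.
#' @export
calibrate_surface <- function(cb_spec, truth = true_surface_spec(),
                              pm_low = NULL, pm_high = NULL,
                              mmt_tol = 0.75) {
  stopifnot(inherits(cb_spec, "crossbasis_spec"))
  p1 <- cb_spec$temp_pctl[["p1"]]
  rng <- cb_spec$temp_range
  if (truth$true_mmt <= rng[1] || truth$true_mmt >= rng[2]) {
    abort(sprintf(
      "requested MMT %.1f C lies outside the observed range (%.1f, %.1f)",
      truth$true_mmt, rng[1], rng[2]), class = "coldmod_calibration_error")
  }

  # front-loaded lag shape projected onto the lag basis
  lags <- seq.int(cb_spec$lag_range[1], cb_spec$lag_range[2])
  C <- lag_basis_matrix(cb_spec)
  w_target <- exp(-lags / 3)
  w_target <- w_target / sum(w_target)
  cvec <- qr.solve(C, w_target)

  # hockey-stick cumulative shape projected onto the temperature basis: a
  # log-linear cold limb (normalised to 1 at the observed P1) meeting a
  # quadratic warm-side upturn that regains `warm_rise` of the cold effect
  # at the observed max — the elbow at the MMT and the warm upturn are what
  # make the minimum identifiable; the projection is constrained to be
  # stationary at the requested MMT so the argmin cannot drift
  grid <- seq(rng[1], rng[2], length.out = 600L)
  g <- ifelse(
    grid <= truth$true_mmt,
    (truth$true_mmt - grid) / (truth$true_mmt - p1),
    truth$warm_rise * ((grid - truth$true_mmt) /
                         (rng[2] - truth$true_mmt))^2
  )
  R <- ns_basis(grid, cb_spec$var_spec)
  Rm <- matrix(ns_basis(truth$true_mmt, cb_spec$var_spec),
               nrow(R), ncol(R), byrow = TRUE)
  h <- 1e-4
  r <- drop(ns_basis(truth$true_mmt + h, cb_spec$var_spec) -
              ns_basis(truth$true_mmt - h, cb_spec$var_spec)) / (2 * h)
  Z <- qr.Q(qr(cbind(r)), complete = TRUE)[, -1, drop = FALSE] # null(r)
  b <- drop(Z %*% qr.solve((R - Rm) %*% Z, g))
  fvals <- drop(R %*% b)
  mmt_star <- max(grid[fvals <= min(fvals) + 1e-12])
  if (abs(mmt_star - truth$true_mmt) > mmt_tol) {
    abort(sprintf(
      paste0("cannot place the curve minimum at %.1f C: projected minimum ",
             "falls at %.1f C (basis too coarse there)"),
      truth$true_mmt, mmt_star), class = "coldmod_calibration_error")
  }

  dR <- drop(ns_basis(p1, cb_spec$var_spec) -
               ns_basis(mmt_star, cb_spec$var_spec))
  SC <- colSums(C)
  K <- sum(dR * b) * sum(SC * cvec)
  if (!is.finite(K) || abs(K) < 1e-12) {
    abort("degenerate calibration: zero cumulative contrast under the shape",
          class = "coldmod_calibration_error")
  }

  if (!is.null(truth$or_low) && !is.null(truth$or_high)) {
    if (is.null(pm_low) || is.null(pm_high)) {
      abort("pm_low and pm_high are required with an (or_low, or_high) pair",
            class = "coldmod_calibration_error")
    }
    delta_unit <- log(truth$or_high / truth$or_low) / (pm_high - pm_low)
    log_or0 <- log(truth$or_low) - pm_low * delta_unit
    target_or_p1 <- exp(log_or0)
    pct_per_10 <- 100 * (exp(10 * delta_unit) - 1)
  } else {
    target_or_p1 <- truth$target_or_p1
    pct_per_10 <- truth$pct_per_10
    delta_unit <- log(1 + pct_per_10 / 100) / 10
  }

  shape <- kronecker(b, cvec) # (j, k) with j outer, matching cb columns
  beta_star <- (log(target_or_p1) / K) * shape
  gamma_star <- (delta_unit / K) * shape
  names(beta_star) <- names(gamma_star) <- crossbasis_colnames(cb_spec)

  a <- cumulative_contrast(cb_spec, p1, mmt_star)
  stopifnot(abs(sum(a * beta_star) - log(target_or_p1)) < 1e-8)

  structure(
    list(beta_star = beta_star, gamma_star = gamma_star,
         theta_pm = truth$theta_pm, true_mmt = mmt_star,
         requested_mmt = truth$true_mmt,
         target_or_p1 = target_or_p1, pct_per_10 = pct_per_10,
         delta_unit = delta_unit, p1_temp = p1,
         pollutant = truth$pollutant, mode = truth$mode,
         subgroup_scale = truth$subgroup_scale,
         lag_weights = drop(C %*% cvec), shape_b = b, shape_c = cvec,
         cb_spec = cb_spec),
    class = "true_surface"
  )
}

#' True modified extreme-cold OR under a calibrated surface
#'
#' Closed-form truth `exp(a' beta_star + p * a' gamma_star)` for the
#' cumulative OR at the 1st temperature percentile vs the true MMT, at
#' pollutant level `p` (omit for the unmodified truth).
#'
#' @param surface A `true_surface`.
#' @param pm_level Optional pollutant concentration.
#' @return Scalar OR.
#' @export
true_extreme_or <- function(surface, pm_level = NULL) {
  a <- cumulative_contrast(surface$cb_spec, surface$p1_temp,
                           surface$true_mmt)
  lo <- sum(a * surface$beta_star)
  if (!is.null(pm_level)) lo <- lo + pm_level * sum(a * surface$gamma_star)
  exp(lo)
}

# Default subgroup shares (independent margins matching the study
# population's reported composition).
subgroup_table <- function() {
  tidyr::expand_grid(
    sex = c("male", "female"),
    age_group = c("<75", ">=75"),
    education = c("low", "high", NA_character_),
    cause_class = c("cardiorespiratory", "other")
  ) |>
    dplyr::mutate(
      share = c(0.5597, 0.4403)[match(.data$sex, c("male", "female"))] *
        c(0.4410, 0.5590)[match(.data$age_group, c("<75", ">=75"))] *
        c(0.8962, 0.0524, 0.0514)[dplyr::coalesce(
          match(.data$education, c("low", "high")), 3L)] *
        c(0.6408, 0.3592)[match(.data$cause_class,
                                c("cardiorespiratory", "other"))]
    )
}

# Interaction scale multiplier of one subgroup row under truth$subgroup_scale.
subgroup_gamma_scale <- function(row, scale_list) {
  if (is.null(scale_list)) return(1)
  s <- 1
  for (v in names(scale_list)) {
    val <- row[[v]]
    if (!is.na(val) && val %in% names(scale_list[[v]])) {
      s <- s * scale_list[[v]][[val]]
    }
  }
  s
}

#' Simulate death records
#'
#' Daily death counts are Poisson with log-rate
#' `log(baseline) + cb(t)' beta_star + theta_pm * PMma(t) +
#' PMma(t) * cb(t)' gamma_star`, centred so the configured baseline is the
#' expected count at reference conditions (temperature history at the MMT,
#' pollutant at its median). Counts are split across demographic subgroups
#' with configurable subgroup-specific interaction strength, and emitted
#' aggregated by (date, region, subgroup) — exposures are shared within a
#' region-day, so the conditional-logistic likelihood depends only on
#' counts.
#'
#' @param config A [sim_config()].
#' @param exposures Output of [simulate_exposures()].
#' @param surface A `true_surface` from [calibrate_surface()].
#' @return Tibble `date`, `region`, `sex`, `age_group`, `education`,
#'   `cause_class`, `n_deaths` (non-zero rows only).
#' @export
simulate_deaths <- function(config, exposures, surface) {
  stopifnot(inherits(config, "sim_config"), inherits(surface, "true_surface"))
  set.seed(child_seed(config$seed, "deaths"))
  spec <- surface$cb_spec
  lag_range <- spec$lag_range
  pm_col <- surface$pollutant
  groups <- subgroup_table()
  gscale <- vapply(seq_len(nrow(groups)),
                   function(i) subgroup_gamma_scale(groups[i, ],
                                                    surface$subgroup_scale),
                   numeric(1))

  out <- purrr::map_dfr(unique(exposures$region), function(rg) {
    ex <- dplyr::arrange(dplyr::filter(exposures, .data$region == rg),
                         .data$date)
    pm_ma <- moving_average(ex[[pm_col]], lag_range)
    if (surface$mode == "spline") {
      cb <- build_crossbasis(ex$temp_c, spec)
      eta_t <- drop(as.matrix(unclass(cb)[, , drop = FALSE]) %*%
                      surface$beta_star)
      mod_t <- drop(as.matrix(unclass(cb)[, , drop = FALSE]) %*%
                      surface$gamma_star)
      cb_ref <- kronecker(
        drop(ns_basis(surface$true_mmt, spec$var_spec)),
        colSums(lag_basis_matrix(spec))
      )
      eta_ref <- sum(cb_ref * surface$beta_star)
      mod_ref <- sum(cb_ref * surface$gamma_star)
    } else {
      # misspecified quadratic surface: per-lag quadratic in lagged
      # temperature with the calibrated front-loaded lag weights
      q <- function(x) ((x - surface$true_mmt) /
                          (surface$p1_temp - surface$true_mmt))^2
      lw <- surface$lag_weights
      lags <- seq.int(lag_range[1], lag_range[2])
      n <- length(ex$temp_c)
      acc <- rep(0, n)
      bad <- rep(FALSE, n)
      for (i in seq_along(lags)) {
        xl <- c(rep(NA_real_, lags[i]), ex$temp_c)[seq_len(n)]
        bad <- bad | !is.finite(xl)
        acc <- acc + lw[i] * q(ifelse(is.finite(xl), xl, 0))
      }
      acc[bad] <- NA_real_
      sw <- sum(lw)
      eta_t <- acc / sw * log(surface$target_or_p1)
      mod_t <- acc / sw * surface$delta_unit
      eta_ref <- 0
      mod_ref <- 0
    }
    at_risk <- ex$in_season & is.finite(eta_t) & is.finite(pm_ma)
    bad_season <- ex$in_season & (!is.finite(eta_t) | !is.finite(pm_ma))
    if (any(bad_season)) {
      first_ok <- ex$date[which(at_risk)[1]]
      abort(paste0("insufficient lead-in days: first in-season day with a ",
                   "complete lag history is ", first_ok),
            class = "coldmod_data_error")
    }
    pm_ref <- stats::median(pm_ma[at_risk])
    idx <- which(at_risk)
    eta0 <- (eta_t[idx] - eta_ref) +
      surface$theta_pm * (pm_ma[idx] - pm_ref)
    modc <- pm_ma[idx] * mod_t[idx] - pm_ref * mod_ref
    purrr::map_dfr(seq_len(nrow(groups)), function(gi) {
      lam <- config$baseline_rate * groups$share[gi] *
        exp(eta0 + gscale[gi] * modc)
      n_d <- rpois(length(idx), lam)
      keep <- n_d > 0L
      if (!any(keep)) return(NULL)
      dplyr::bind_cols(
        tibble(date = ex$date[idx][keep], region = rg),
        groups[rep(gi, sum(keep)), c("sex", "age_group", "education",
                                     "cause_class")],
        tibble(n_deaths = n_d[keep])
      )
    })
  })
  dplyr::arrange(out, .data$region, .data$date)
}

#' Simulate a complete study
#'
#' Exposures, calibrated truth and death records in one call: simulates
#' weather and pollutants, resolves the crossbasis from the in-season
#' temperatures, calibrates the generative surface to the configured truth
#' (pinning `(or_low, or_high)` at the pollutant's simulated 10th/90th
#' percentiles when that mode is used), and draws Poisson deaths.
#'
#' @param config A [sim_config()].
#' @param var_df,lag_df,max_lag Crossbasis dimensions of the truth (and, for
#'   well-specified recovery, of the estimator), defaults 3/4/12.
#' @return List of class `cold_sim`: `exposures`, `deaths`, `surface`,
#'   `config`.
#' @export
simulate_study <- function(config, var_df = 3L, lag_df = 4L, max_lag = 12L) {
  exposures <- simulate_exposures(config)
  in_season <- exposures$in_season
  cb_spec <- crossbasis_spec(exposures$temp_c[in_season],
                             var_df = var_df, lag_df = lag_df,
                             lag_range = c(0L, max_lag))
  truth <- config$truth
  pm_daily <- exposures[[truth$pollutant]][in_season]
  surface <- calibrate_surface(
    cb_spec, truth,
    pm_low = pctl(pm_daily, .10), pm_high = pctl(pm_daily, .90)
  )
  deaths <- simulate_deaths(config, exposures, surface)
  structure(list(exposures = exposures, deaths = deaths,
                 surface = surface, config = config),
            class = "cold_sim")
}

#' Expand aggregated death records to one row per death
#'
#' @param deaths Aggregated deaths with `n_deaths`.
#' @return Tibble with one row per death and no `n_deaths` column.
#' @export
expand_deaths <- function(deaths) {
  out <- deaths[rep(seq_len(nrow(deaths)), deaths$n_deaths), , drop = FALSE]
  out$n_deaths <- NULL
  as_tibble(out)
}

#' Write a simulated study to delimited text files
#'
#' Writes `exposures.csv` (date, region, temp_c, rh_pct, pm1, pm25, ozone)
#' and `deaths.csv` (date, region, n_deaths, sex, age_group, education,
#' cause_class), ISO-8601 dates, UTF-8, with header rows.
#'
#' @param sim A `cold_sim` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "cold_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ef <- file.path(dir, "exposures.csv")
  df <- file.path(dir, "deaths.csv")
  utils::write.csv(
    sim$exposures[c("date", "region", "temp_c", "rh_pct", "pm1", "pm25",
                    "ozone")],
    ef, row.names = FALSE)
  utils::write.csv(
    sim$deaths[c("date", "region", "n_deaths", "sex", "age_group",
                 "education", "cause_class")],
    df, row.names = FALSE)
  invisible(c(exposures = ef, deaths = df))
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `exposures.csv` and `deaths.csv`.
#' @return List with `exposures` and `deaths` tibbles (ISO dates parsed).
#' @export
read_study <- function(dir) {
  ex <- as_tibble(utils::read.csv(file.path(dir, "exposures.csv")))
  de <- as_tibble(utils::read.csv(file.path(dir, "deaths.csv")))
  ex$date <- as.Date(ex$date)
  de$date <- as.Date(de$date)
  list(exposures = ex, deaths = de)
}
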