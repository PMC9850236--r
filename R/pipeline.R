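# End-to-end orchestration: descriptive summary, main fit per pollutant,
# stratified analyses, sensitivity battery.

#' Analysis configuration
#'
#' All tunable parameters of one model set: the modifying pollutant, the
#' crossbasis dimensions (temperature df 3, lag df 4, maximum lag 12 days),
#' the humidity spline df (3), the cold-season months, the pollutant
#' centering percentiles (10/50/90) and the extreme-cold percentile (1st).
#'
#' @param pollutant `"pm1"` or `"pm25"`.
#' @param max_lag Maximum temperature lag in days (default 12).
#' @param var_df,lag_df Crossbasis degrees of freedom (defaults 3, 4).
#' @param rh_df Humidity spline df (default 3).
#' @param season_months Cold-season months (default Nov-Feb).
#' @param centering Pollutant centering percentiles as probabilities
#'   (default `c(0.10, 0.50, 0.90)`).
#' @param extreme_pct Extreme-cold percentile (default 0.01).
#' @param adjust_ozone Add an ozone moving-average adjustment term.
#' @param var_knots,lag_knots Optional explicit crossbasis knots (data/lag
#'   units) for sensitivity variants.
#' @param grid_step Temperature grid step for curves and the MMT search
#'   (default 0.1 C).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(pollutant = c("pm1", "pm25"),
                            max_lag = 12L, var_df = 3L, lag_df = 4L,
                            rh_df = 3L,
                            season_months = c(11L, 12L, 1L, 2L),
                            centering = c(0.10, 0.50, 0.90),
                            extreme_pct = 0.01,
                            adjust_ozone = FALSE,
                            var_knots = NULL, lag_knots = NULL,
                            grid_step = 0.1) {
  if (max_lag < 1) abort("max_lag must be >= 1",
                         class = "coldmod_config_error")
  if (any(centering <= 0 | centering >= 1) || extreme_pct <= 0 ||
      extreme_pct >= 1) {
    abort("percentiles must lie in (0, 1)", class = "coldmod_config_error")
  }
  structure(
    list(pollutant = match.arg(pollutant), max_lag = as.integer(max_lag),
         var_df = as.integer(var_df), lag_df = as.integer(lag_df),
         rh_df = as.integer(rh_df),
         season_months = as.integer(season_months),
         centering = centering, extreme_pct = extreme_pct,
         adjust_ozone = adjust_ozone,
         var_knots = var_knots, lag_knots = lag_knots,
         grid_step = grid_step),
    class = "analysis_config"
  )
}

#' Descriptive summary of deaths and exposures
#'
#' Counts and percentages of deaths by demographic subgroup, and
#' 25th/50th/75th percentiles of temperature and each pollutant over
#' in-season days.
#'
#' @param deaths Death records (aggregated or per-death).
#' @param exposures Daily exposure series.
#' @param season_months Cold-season months.
#' @return List of class `cold_summary` with `deaths` (variable, level, n,
#'   pct) and `environment` (variable, p25, p50, p75) tibbles.
#' @export
summarize_data <- function(deaths, exposures,
                           season_months = c(11L, 12L, 1L, 2L)) {
  if (!nrow(deaths) || !nrow(exposures)) {
    abort("empty input", class = "coldmod_data_error")
  }
  deaths <- as_tibble(deaths)
  deaths$date <- as.Date(deaths$date)
  if (!"n_deaths" %in% names(deaths)) deaths$n_deaths <- 1L
  deaths <- deaths[month_of(deaths$date) %in% season_months, , drop = FALSE]
  total <- sum(deaths$n_deaths)
  vars <- intersect(c("sex", "age_group", "education", "cause_class"),
                    names(deaths))
  dsum <- purrr::map_dfr(vars, function(v) {
    deaths |>
      dplyr::group_by(level = dplyr::coalesce(as.character(.data[[v]]),
                                              "missing")) |>
      dplyr::summarise(n = sum(.data$n_deaths), .groups = "drop") |>
      dplyr::mutate(variable = v, pct = 100 * .data$n / total, .before = 1)
  })
  exposures <- as_tibble(exposures)
  exposures$date <- as.Date(exposures$date)
  inseas <- exposures[month_of(exposures$date) %in% season_months, ,
                      drop = FALSE]
  env_vars <- intersect(c("temp_c", "pm1", "pm25", "ozone", "rh_pct"),
                        names(inseas))
  esum <- purrr::map_dfr(env_vars, function(v) {
    q <- pctl(inseas[[v]], c(.25, .50, .75))
    tibble(variable = v, p25 = q[1], p50 = q[2], p75 = q[3])
  })
  structure(list(deaths = dsum, total_deaths = total, environment = esum),
            class = "cold_summary")
}

#' @export
print.cold_summary <- function(x, ...) {
  cat("Cold-season deaths:", x$total_deaths, "\n")
  print(as.data.frame(x$deaths), row.names = FALSE)
  cat("\nEnvironment (in-season percentiles):\n")
  print(as.data.frame(x$environment), row.names = FALSE)
  invisible(x)
}

#' Run one full model set
#'
#' Builds the crossbasis and design table for the configured pollutant, fits
#' the conditional-logistic model, and reduces it: overall cumulative curve
#' (evaluated at the median pollutant level), MMT, extreme-cold OR,
#' pollutant-modified ORs at the centering levels, percent change per
#' 10 ug/m3, and the lag-response pattern.
#'
#' @param deaths,exposures Input tables (see [build_design()]).
#' @param config An [analysis_config()].
#' @param strata_by Subgroup columns for stratum aggregation (default none:
#'   overall analysis).
#' @return List of class `cold_report`: `config`, `summary`, `fit`, `mmt`,
#'   `curve`, `extreme_cold`, `modification`, `lag`, `pct_per_10`,
#'   `accounting`.
#' @export
run_analysis <- function(deaths, exposures, config = analysis_config(),
                         strata_by = character()) {
  stopifnot(inherits(config, "analysis_config"))
  design <- build_design(
    deaths, exposures, pollutant = config$pollutant,
    rh_df = config$rh_df, season_months = config$season_months,
    strata_by = strata_by, adjust_ozone = config$adjust_ozone,
    max_lag = config$max_lag, var_df = config$var_df,
    lag_df = config$lag_df, centering = config$centering,
    cb_spec = {
      ins <- month_of(as.Date(exposures$date)) %in% config$season_months
      crossbasis_spec(exposures$temp_c[ins], var_df = config$var_df,
                      lag_df = config$lag_df,
                      lag_range = c(0L, config$max_lag),
                      var_knots = config$var_knots,
                      lag_knots = config$lag_knots)
    }
  )
  fit <- conditional_logistic_fit(design)
  spec <- fit$cb_spec
  grid <- seq(spec$temp_pctl[["p1"]], spec$temp_range[2],
              by = config$grid_step)
  pm_med <- unname(fit$pm_pctl[ceiling(length(fit$pm_pctl) / 2)])
  mmt <- find_mmt(cumulative_curve(fit, ref_temp = grid[1], grid = grid,
                                   pm_level = pm_med))
  curve <- cumulative_curve(fit, ref_temp = mmt, grid = grid,
                            pm_level = pm_med)
  levels <- stats::setNames(
    unname(fit$pm_pctl),
    c("low", "median", "high")[seq_along(fit$pm_pctl)]
  )
  modification <- modification_summary(fit, levels = levels, ref_temp = mmt)
  report <- list(
    config = config,
    summary = summarize_data(deaths, exposures, config$season_months),
    fit = fit,
    mmt = mmt,
    curve = curve,
    extreme_cold = extreme_cold_or(curve),
    modification = modification,
    pct_per_10 = modification$pct_per_10,
    lag = lag_response(fit, x0 = mmt, pm_level = pm_med),
    accounting = fit$drops
  )
  class(report) <- "cold_report"
  report
}


#' @export
print.cold_report <- function(x, ...) {
  e <- x$extreme_cold
  cat(sprintf(
    "Cold effect (%s model set): MMT %.1f C; OR at %.1f C: %.2f (%.2f, %.2f)\n",
    toupper(x$config$pollutant), x$mmt, e$temp, e$or, e$conf_low,
    e$conf_high))
  print(x$modification)
  invisible(x)
}

#' @describeIn run_analysis One-row headline summary of a report.
#' @method glance cold_report
#' @param x A `cold_report`.
#' @param ... Unused.
#' @export
glance.cold_report <- function(x, ...) {
  e <- x$extreme_cold
  p <- x$pct_per_10
  tibble(
    pollutant = x$config$pollutant,
    n_strata = x$fit$n_strata,
    n_weighted_cases = x$fit$n_weighted_cases,
    mmt = x$mmt,
    or_p1 = e$or, or_conf_low = e$conf_low, or_conf_high = e$conf_high,
    pct_per_10 = p$pct, pct_conf_low = p$conf_low,
    pct_conf_high = p$conf_high
  )
}

#' Stratified analyses
#'
#' Independent model fits per subgroup level (gender, age group, education,
#' cause of death), reporting the percent change in the extreme-cold OR per
#' 10 ug/m3 with its CI, formatted as in the study's subgroup table. Deaths
#' with missing education are excluded only from the education strata; a
#' subgroup whose fit fails is reported as missing and the run continues.
#'
#' @param deaths,exposures Input tables.
#' @param config An [analysis_config()].
#' @param variables Subgroup variables to stratify on.
#' @return Tibble: `variable`, `level`, `pollutant`, `pct`, `conf_low`,
#'   `conf_high`, `formatted`, `or_p1`, `n_deaths`.
#' @export
run_stratified <- function(deaths, exposures, config = analysis_config(),
                           variables = c("sex", "age_group", "education",
                                         "cause_class")) {
  deaths <- as_tibble(deaths)
  variables <- intersect(variables, names(deaths))
  rows <- purrr::map_dfr(c("overall", variables), function(v) {
    lvls <- if (v == "overall") "overall" else
      sort(unique(stats::na.omit(deaths[[v]])))
    purrr::map_dfr(lvls, function(lv) {
      d <- if (v == "overall") deaths else
        deaths[!is.na(deaths[[v]]) & deaths[[v]] == lv, , drop = FALSE]
      res <- tryCatch(run_analysis(d, exposures, config), error = identity)
      if (inherits(res, "error")) {
        return(tibble(variable = v, level = lv,
                      pollutant = config$pollutant,
                      pct = NA_real_, conf_low = NA_real_,
                      conf_high = NA_real_, formatted = NA_character_,
                      or_p1 = NA_real_, n_deaths = sum(d$n_deaths %||% 1)))
      }
      p <- res$pct_per_10
      tibble(
        variable = v, level = lv, pollutant = config$pollutant,
        pct = p$pct, conf_low = p$conf_low, conf_high = p$conf_high,
        formatted = sprintf("%.1f (%.1f, %.1f)", p$pct, p$conf_low,
                            p$conf_high),
        or_p1 = res$extreme_cold$or,
        n_deaths = res$fit$n_weighted_cases
      )
    })
  })
  rows
}

#' Sensitivity battery
#'
#' Re-runs the analysis under each variant configuration — maximum lag 10 to
#' 18 days, alternative crossbasis knots, humidity spline df 4, ozone
#' adjustment — and tabulates the extreme-cold OR and percent change per
#' 10 ug/m3 beside the base case. Per-variant failures are logged and the
#' others continue.
#'
#' @param deaths,exposures Input tables.
#' @param config Base [analysis_config()].
#' @param variants Named list of configs; `NULL` builds the default battery.
#' @return Tibble: `variant`, `mmt`, `or_p1`, `or_conf_low`,
#'   `or_conf_high`, `pct`, `pct_conf_low`, `pct_conf_high`, `error`.
#' @export
run_sensitivity <- function(deaths, exposures, config = analysis_config(),
                            variants = NULL) {
  if (is.null(variants)) {
    variants <- c(
      stats::setNames(
        purrr::map(10:18, function(l) modify_config(config, max_lag = l)),
        paste0("max_lag_", 10:18)
      ),
      list(
        var_df_4 = modify_config(config, var_df = 4L),
        lag_df_5 = modify_config(config, lag_df = 5L),
        rh_df_4 = modify_config(config, rh_df = 4L),
        ozone_adjusted = modify_config(config, adjust_ozone = TRUE)
      )
    )
  }
  base <- list(base = config)
  purrr::imap_dfr(c(base, variants), function(cfg, nm) {
    res <- tryCatch(run_analysis(deaths, exposures, cfg), error = identity)
    if (inherits(res, "error")) {
      return(tibble(variant = nm, mmt = NA_real_, or_p1 = NA_real_,
                    or_conf_low = NA_real_, or_conf_high = NA_real_,
                    pct = NA_real_, pct_conf_low = NA_real_,
                    pct_conf_high = NA_real_,
                    error = conditionMessage(res)))
    }
    g <- glance(res)
    tibble(variant = nm, mmt = g$mmt, or_p1 = g$or_p1,
           or_conf_low = g$or_conf_low, or_conf_high = g$or_conf_high,
           pct = g$pct_per_10, pct_conf_low = g$pct_conf_low,
           pct_conf_high = g$pct_conf_high, error = NA_character_)
  })
}

# Return a copy of an analysis_config with fields replaced.
modify_config <- function(config, ...) {
  repl <- list(...)
  for (nm in names(repl)) config[[nm]] <- repl[[nm]]
  config
}
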