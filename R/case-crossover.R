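#' Time-stratified referent days
#'
#' Referent (control) days for a case day under the time-stratified scheme:
#' all days of the same calendar year and month that share the case day's
#' weekday, excluding the case day itself. The scheme is bidirectional
#' (referents fall both before and after the case day) and yields 3 or 4
#' referents in months of 28-31 days.
#'
#' @param case_date A `Date` (length 1).
#' @return Ascending `Date` vector of referent days.
#' @examples
#' referent_days(as.Date("2015-01-15"))
#' @export
referent_days <- function(case_date) {
  case_date <- as.Date(case_date)
  stopifnot(length(case_date) == 1L, !is.na(case_date))
  first <- as.Date(format(case_date, "%Y-%m-01"))
  last <- seq(first, by = "1 month", length.out = 2L)[2L] - 1L
  days <- seq(first, last, by = "day")
  sort(days[iso_wday(days) == iso_wday(case_date) & days != case_date])
}

# Daily covariate table for one region: crossbasis columns, RH moving
# average, pollutant moving averages (daily values kept for percentile
# thresholds). `complete` marks days usable as case or referent days.
region_covariates <- function(exp_r, cb_spec, lag_range) {
  exp_r <- dplyr::arrange(exp_r, .data$date)
  full <- tibble(date = seq(min(exp_r$date), max(exp_r$date), by = "day"))
  exp_r <- dplyr::left_join(full, exp_r, by = "date")
  cb <- build_crossbasis(exp_r$temp_c, cb_spec)
  out <- tibble(
    date = exp_r$date,
    temp_c = exp_r$temp_c,
    rh_ma = moving_average(exp_r$rh_pct, lag_range),
    pm1 = exp_r$pm1,
    pm25 = exp_r$pm25,
    pm1_ma = moving_average(exp_r$pm1, lag_range),
    pm25_ma = moving_average(exp_r$pm25, lag_range)
  )
  if ("ozone" %in% names(exp_r) && !all(is.na(exp_r$ozone))) {
    out$oz_ma <- moving_average(exp_r$ozone, lag_range)
  }
  dplyr::bind_cols(out, as_tibble(unclass(cb)[, , drop = FALSE]))
}

#' Assemble the case-crossover design table
#'
#' Aggregates deaths into strata (one per region, case date and analysis
#' subgroup, weighted by the death count), attaches the time-stratified
#' referent days, and joins every regressor of the conditional-logistic
#' model: temperature crossbasis columns, a natural cubic spline of the
#' lag 0-12 moving average of relative humidity, the linear moving average of
#' the chosen pollutant, the crossbasis-by-pollutant interaction columns, and
#' optionally an ozone moving-average adjustment. Strata touching any day
#' with incomplete covariates (or outside exposure coverage) are dropped
#' whole and accounted for.
#'
#' @param deaths Data frame with `date`, `region` and either `n_deaths`
#'   (aggregated counts) or one row per death; optional subgroup columns
#'   (`sex`, `age_group`, `education`, `cause_class`).
#' @param exposures Data frame with `date`, `region`, `temp_c`, `rh_pct`,
#'   `pm1`, `pm25`, optionally `ozone`, on consecutive days (including the
#'   lag lead-in before the first case day).
#' @param pollutant `"pm1"` or `"pm25"` — the modifying pollutant of this
#'   model set.
#' @param cb_spec Optional [crossbasis_spec()]; resolved from the pooled
#'   in-season temperatures when `NULL`.
#' @param rh_df Degrees of freedom of the humidity spline (default 3).
#' @param season_months Calendar months defining the cold season
#'   (default November-February).
#' @param strata_by Character vector of subgroup columns used in the stratum
#'   definition; empty (default) aggregates all deaths of a region-day.
#' @param adjust_ozone Add the ozone moving average as a linear term.
#' @param max_lag Maximum lag in days (default 12); ignored when `cb_spec`
#'   is supplied.
#' @param centering Probabilities of the pollutant centering percentiles
#'   stored on the design (default `c(0.10, 0.50, 0.90)`).
#' @param var_df,lag_df Crossbasis dimensions when `cb_spec` is `NULL`.
#' @return A tibble of class `cold_design`: one row per stratum-day with
#'   `stratum`, `region`, `date`, `is_case`, `weight` and all regressor
#'   columns. Attributes carry the resolved basis specs, pollutant
#'   percentiles and dropped-strata accounting.
#' @export
build_design <- function(deaths, exposures,
                         pollutant = c("pm1", "pm25"),
                         cb_spec = NULL, rh_df = 3L,
                         season_months = c(11L, 12L, 1L, 2L),
                         strata_by = character(),
                         adjust_ozone = FALSE,
                         max_lag = 12L, var_df = 3L, lag_df = 4L,
                         centering = c(0.10, 0.50, 0.90)) {
  pollutant <- match.arg(pollutant)
  deaths <- as_tibble(deaths)
  exposures <- as_tibble(exposures)
  for (nm in c("date", "region")) {
    if (!nm %in% names(deaths) || !nm %in% names(exposures)) {
      abort(paste0("both inputs need a `", nm, "` column"),
            class = "coldmod_data_error")
    }
  }
  deaths$date <- as.Date(deaths$date)
  exposures$date <- as.Date(exposures$date)
  if (!"n_deaths" %in% names(deaths)) deaths$n_deaths <- 1L
  if (adjust_ozone && !"ozone" %in% names(exposures)) {
    abort("ozone adjustment requested but no `ozone` column",
          class = "coldmod_data_error")
  }

  in_season <- month_of(exposures$date) %in% season_months
  if (is.null(cb_spec)) {
    cb_spec <- crossbasis_spec(exposures$temp_c[in_season],
                               var_df = var_df, lag_df = lag_df,
                               lag_range = c(0L, max_lag))
  }
  lag_range <- cb_spec$lag_range

  # strata: aggregate deaths over (region, date, subgroup)
  keep <- month_of(deaths$date) %in% season_months
  n_out_of_season <- sum(deaths$n_deaths[!keep])
  deaths <- deaths[keep, , drop = FALSE]
  if (length(strata_by)) {
    missing_cols <- setdiff(strata_by, names(deaths))
    if (length(missing_cols)) {
      abort(paste0("missing subgroup columns: ",
                   paste(missing_cols, collapse = ", ")),
            class = "coldmod_data_error")
    }
  }
  strata <- deaths |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("region", "date", strata_by)))) |>
    dplyr::summarise(weight = sum(.data$n_deaths), .groups = "drop") |>
    dplyr::mutate(stratum = dplyr::row_number())
  if (!nrow(strata)) {
    abort("no cold-season deaths to analyse", class = "coldmod_data_error")
  }

  # expand to stratum-days
  case_dates <- unique(strata$date)
  ref_map <- tibble(
    date = case_dates,
    ref = lapply(case_dates, referent_days)
  )
  rows <- strata |>
    dplyr::left_join(ref_map, by = "date") |>
    dplyr::rename(case_date = "date") |>
    dplyr::mutate(days = purrr::map2(.data$case_date, .data$ref,
                                     ~ c(.x, .y))) |>
    dplyr::select(-"ref") |>
    tidyr::unnest_longer("days", values_to = "date") |>
    dplyr::mutate(is_case = as.integer(.data$date == .data$case_date))

  # covariates per region
  cov <- exposures |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(~ region_covariates(.x, cb_spec, lag_range)) |>
    dplyr::ungroup()

  rows <- dplyr::left_join(rows, cov, by = c("region", "date"))

  cb_cols <- crossbasis_colnames(cb_spec)
  rh_spec <- spline_spec(cov$rh_ma[month_of(cov$date) %in% season_months],
                         df = rh_df)
  pm_col <- paste0(pollutant, "_ma")
  need <- c(cb_cols, "rh_ma", pm_col, if (adjust_ozone) "oz_ma")
  bad_stratum <- rows |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(
      drop = anyNA(dplyr::pick(dplyr::all_of(need))),
      .groups = "drop"
    )
  dropped <- strata |>
    dplyr::inner_join(dplyr::filter(bad_stratum, .data$drop), by = "stratum")
  rows <- rows |>
    dplyr::anti_join(dplyr::filter(bad_stratum, .data$drop), by = "stratum")
  if (!nrow(rows)) {
    abort("no stratum has complete covariates on all its days",
          class = "coldmod_data_error")
  }

  rh_mat <- ns_basis(rows$rh_ma, rh_spec)
  colnames(rh_mat) <- paste0("rh", seq_len(rh_df))
  int_mat <- as.matrix(rows[cb_cols]) * rows[[pm_col]]
  colnames(int_mat) <- sub("^cb", "i", cb_cols)

  design <- dplyr::bind_cols(
    dplyr::select(rows, "stratum", "region", "date", "case_date",
                  dplyr::all_of(strata_by), "is_case", "weight",
                  dplyr::all_of(cb_cols)),
    as_tibble(rh_mat),
    tibble(pm = rows[[pm_col]]),
    as_tibble(int_mat)
  )
  if (adjust_ozone) design$oz <- rows$oz_ma

  season_cov <- cov[month_of(cov$date) %in% season_months, , drop = FALSE]
  col_groups <- list(
    cb = cb_cols, rh = colnames(rh_mat), pm = "pm",
    interaction = colnames(int_mat), extra = if (adjust_ozone) "oz"
  )
  structure(
    design,
    class = c("cold_design", class(design)),
    cb_spec = cb_spec, rh_spec = rh_spec, pollutant = pollutant,
    col_groups = col_groups,
    pm_pctl = stats::setNames(
      pctl(season_cov[[pollutant]], centering),
      paste0("p", round(100 * centering))
    ),
    drops = tibble(
      reason = c("outside_season", "incomplete_covariates"),
      n_strata = c(NA_integer_, nrow(dropped)),
      n_deaths = c(n_out_of_season, sum(dropped$weight))
    ),
    n_input_deaths = sum(strata$weight) + n_out_of_season,
    n_used_deaths = sum(strata$weight) - sum(dropped$weight)
  )
}
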