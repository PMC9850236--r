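# Reduction of fitted crossbasis coefficients to summaries: cumulative
# exposure-response curves, MMT, pollutant-modified cold effects, percent
# change per 10 ug/m3, lag-response patterns.

#' Cumulative temperature contrast vector
#'
#' The vector `a` with `a[(j,k)] = (R_j(x1) - R_j(x0)) * sum_l C_k(l)`, so
#' that `a' beta` is the cumulative (lag-summed) log-OR of temperature `x1`
#' versus `x0` and `a' V a` its variance. Ordered to match the crossbasis
#' columns.
#'
#' @param cb_spec A [crossbasis_spec()].
#' @param x1,x0 Temperatures (degrees C).
#' @return Numeric vector of length `var_df * lag_df`.
#' @export
cumulative_contrast <- function(cb_spec, x1, x0) {
  dR <- ns_basis(x1, cb_spec$var_spec) - ns_basis(x0, cb_spec$var_spec)
  SC <- colSums(lag_basis_matrix(cb_spec))
  drop(kronecker(drop(dR), SC))
}

# Extract the crossbasis block of beta and the relevant covariance blocks.
# At pollutant level p the effective coefficients are beta + p * gamma with
# covariance V_bb + p^2 V_gg + 2 p V_bg.
effective_cb <- function(fit, pm_level = NULL) {
  cb_cols <- fit$col_groups$cb
  b <- fit$beta[cb_cols]
  V <- fit$vcov[cb_cols, cb_cols, drop = FALSE]
  if (!is.null(pm_level)) {
    int_cols <- fit$col_groups$interaction
    if (is.null(int_cols) || !all(int_cols %in% names(fit$beta))) {
      abort("fit has no crossbasis-by-pollutant interaction columns",
            class = "coldmod_spec_error")
    }
    g <- fit$beta[int_cols]
    Vgg <- fit$vcov[int_cols, int_cols, drop = FALSE]
    Vbg <- fit$vcov[cb_cols, int_cols, drop = FALSE]
    b <- b + pm_level * g
    V <- V + pm_level^2 * Vgg + pm_level * (Vbg + t(Vbg))
  }
  if (anyNA(b)) {
    abort("crossbasis coefficients contain aliased (NA) entries",
          class = "coldmod_fit_error")
  }
  list(b = b, V = V)
}

default_grid <- function(cb_spec, step = 0.1) {
  # observed 1st percentile extended to the observed maximum
  seq(cb_spec$temp_pctl[["p1"]], cb_spec$temp_range[2], by = step)
}

#' Cumulative exposure-response curve
#'
#' Evaluates the lag-cumulated log-OR of each grid temperature against a
#' reference temperature, with delta-method standard errors; at a pollutant
#' level `pm_level` the curve uses the effective coefficients
#' `beta + p * gamma` (the pollutant-modified curve).
#'
#' @param fit A `cold_clogit` fit.
#' @param ref_temp Reference temperature (degrees C); typically the MMT.
#' @param grid Temperature grid; default 0.1 degree steps from the observed
#'   1st percentile to the observed maximum.
#' @param pm_level Optional pollutant concentration (ug/m3) at which to
#'   centre the curve; `NULL` gives the main-effects curve.
#' @return A tibble of class `er_curve` with `temp`, `log_or`, `se`, `or`,
#'   `conf_low`, `conf_high`; attributes keep `ref_temp`, `pm_level` and the
#'   basis spec.
#' @export
cumulative_curve <- function(fit, ref_temp, grid = NULL, pm_level = NULL) {
  stopifnot(inherits(fit, "cold_clogit"))
  if (!fit$converged) abort("fit did not converge",
                            class = "coldmod_fit_error")
  spec <- fit$cb_spec
  grid <- grid %||% default_grid(spec)
  if (ref_temp < min(grid) - 1e-8 || ref_temp > max(grid) + 1e-8) {
    abort("reference temperature outside the curve grid",
          class = "coldmod_spec_error")
  }
  eff <- effective_cb(fit, pm_level)
  dR <- ns_basis(grid, spec$var_spec) -
    matrix(ns_basis(ref_temp, spec$var_spec), length(grid), spec$var_spec$df,
           byrow = TRUE)
  SC <- colSums(lag_basis_matrix(spec))
  A <- dR[, rep(seq_len(spec$var_spec$df), each = spec$lag_spec$df),
          drop = FALSE] *
    matrix(rep(SC, spec$var_spec$df), length(grid), length(eff$b),
           byrow = TRUE)
  log_or <- drop(A %*% eff$b)
  se <- sqrt(pmax(rowSums((A %*% eff$V) * A), 0))
  out <- tibble(
    temp = grid, log_or = log_or, se = se,
    or = exp(log_or),
    conf_low = exp(log_or - 1.96 * se),
    conf_high = exp(log_or + 1.96 * se)
  )
  structure(out, class = c("er_curve", class(out)),
            ref_temp = ref_temp, pm_level = pm_level, cb_spec = spec,
            p1_temp = spec$temp_pctl[["p1"]])
}

#' Minimum mortality temperature
#'
#' Argmin of the cumulative log-OR curve over a dense grid (default 0.1
#' degrees C from the observed 1st percentile to the observed maximum). The
#' location is invariant to the provisional reference used to build the
#' curve; ties break toward the warmer temperature.
#'
#' @param x A `cold_clogit` fit or an `er_curve`.
#' @param grid Optional temperature grid (fit method).
#' @param ... Unused.
#' @return MMT in degrees C (scalar).
#' @export
find_mmt <- function(x, ...) UseMethod("find_mmt")

#' @rdname find_mmt
#' @export
find_mmt.cold_clogit <- function(x, grid = NULL, ...) {
  grid <- grid %||% default_grid(x$cb_spec)
  ref <- grid[1] # provisional; argmin does not depend on it
  find_mmt(cumulative_curve(x, ref_temp = ref, grid = grid))
}

#' @rdname find_mmt
#' @export
find_mmt.er_curve <- function(x, ...) {
  if (!all(is.finite(x$log_or))) {
    abort("non-finite curve values", class = "coldmod_fit_error")
  }
  lo <- min(x$log_or)
  max(x$temp[x$log_or <= lo + 1e-12]) # warmest tied minimiser
}

#' Extreme-cold cumulative odds ratio
#'
#' The cumulative OR (with 95% CI, computed on the log scale and
#' exponentiated) at the extreme cold temperature — by default the 1st
#' percentile of the observed cold-season temperatures — versus the curve's
#' reference.
#'
#' @param curve An `er_curve` (reference at the MMT for the conventional
#'   estimate).
#' @param at Temperature at which to read the curve; default the observed
#'   1st percentile stored in the curve.
#' @return One-row tibble: `temp`, `ref_temp`, `pm_level`, `or`, `conf_low`,
#'   `conf_high`.
#' @export
extreme_cold_or <- function(curve, at = NULL) {
  stopifnot(inherits(curve, "er_curve"))
  at <- at %||% attr(curve, "p1_temp")
  i <- which.min(abs(curve$temp - at))
  tibble(
    temp = curve$temp[i], ref_temp = attr(curve, "ref_temp"),
    pm_level = attr(curve, "pm_level") %||% NA_real_,
    or = curve$or[i], conf_low = curve$conf_low[i],
    conf_high = curve$conf_high[i]
  )
}

#' Percent change in the extreme-cold OR per 10 ug/m3 of pollutant
#'
#' From the interaction coefficients: `delta = a(x1, x0)' gamma`, percent
#' change `100 * (exp(10 * delta) - 1)` with the delta-method CI computed on
#' the log scale, `se_delta = sqrt(a' V_gg a)`.
#'
#' @param fit A `cold_clogit` with interaction columns.
#' @param x1 Cold temperature (default the observed 1st percentile).
#' @param x0 Reference temperature (default the fitted MMT).
#' @return One-row tibble: `x1`, `x0`, `delta`, `pct`, `conf_low`,
#'   `conf_high`.
#' @export
pct_change_per_10 <- function(fit, x1 = NULL, x0 = NULL) {
  stopifnot(inherits(fit, "cold_clogit"))
  int_cols <- fit$col_groups$interaction
  if (is.null(int_cols)) {
    abort("fit has no interaction columns", class = "coldmod_spec_error")
  }
  x1 <- x1 %||% fit$cb_spec$temp_pctl[["p1"]]
  x0 <- x0 %||% find_mmt(fit)
  a <- cumulative_contrast(fit$cb_spec, x1, x0)
  g <- fit$beta[int_cols]
  if (anyNA(g)) abort("aliased interaction coefficients",
                      class = "coldmod_fit_error")
  delta <- sum(a * g)
  se <- sqrt(max(drop(t(a) %*% fit$vcov[int_cols, int_cols] %*% a), 0))
  tibble(
    x1 = x1, x0 = x0, delta = delta,
    pct = 100 * (exp(10 * delta) - 1),
    conf_low = 100 * (exp(10 * (delta - 1.96 * se)) - 1),
    conf_high = 100 * (exp(10 * (delta + 1.96 * se)) - 1)
  )
}

#' Lag-response pattern at a fixed temperature contrast
#'
#' Lag-specific log-ORs of `x1` versus `x0`: at lag `l` the contribution is
#' `sum_{j,k} (R_j(x1) - R_j(x0)) C_k(l) beta[(j,k)]`, so the integer-lag
#' sum reproduces the cumulative log-OR exactly. At a pollutant level the
#' effective coefficients `beta + p * gamma` are used.
#'
#' @param fit A `cold_clogit`.
#' @param x1,x0 Temperature contrast (defaults: observed P1 vs fitted MMT).
#' @param pm_level Optional pollutant level.
#' @return Tibble of class `lag_curve`: `lag`, `log_or`, `se`, `or`,
#'   `conf_low`, `conf_high`.
#' @export
lag_response <- function(fit, x1 = NULL, x0 = NULL, pm_level = NULL) {
  stopifnot(inherits(fit, "cold_clogit"))
  spec <- fit$cb_spec
  x1 <- x1 %||% spec$temp_pctl[["p1"]]
  x0 <- x0 %||% find_mmt(fit)
  eff <- effective_cb(fit, pm_level)
  dR <- drop(ns_basis(x1, spec$var_spec) - ns_basis(x0, spec$var_spec))
  C <- lag_basis_matrix(spec)
  lags <- seq.int(spec$lag_range[1], spec$lag_range[2])
  A <- t(vapply(seq_along(lags),
                function(i) kronecker(dR, C[i, ]),
                numeric(length(eff$b))))
  log_or <- drop(A %*% eff$b)
  se <- sqrt(pmax(rowSums((A %*% eff$V) * A), 0))
  out <- tibble(
    lag = lags, log_or = log_or, se = se, or = exp(log_or),
    conf_low = exp(log_or - 1.96 * se),
    conf_high = exp(log_or + 1.96 * se)
  )
  structure(out, class = c("lag_curve", class(out)),
            x1 = x1, x0 = x0, pm_level = pm_level)
}

#' Pollutant-modified extreme-cold effects
#'
#' Evaluates the extreme-cold cumulative OR at the pollutant's low, median
#' and high centering levels (10th/50th/90th percentiles of the daily
#' in-season concentrations by default) and the percent change per
#' 10 ug/m3, all against a common reference (the MMT of the main-effects
#' curve at the median pollutant level).
#'
#' @param fit A `cold_clogit` with interaction columns.
#' @param levels Named numeric vector of centering concentrations; defaults
#'   to the percentiles stored in the fit.
#' @param ref_temp Common reference temperature; default the MMT of the
#'   curve at the median pollutant level.
#' @param x1 Extreme cold temperature; default observed P1.
#' @return Object of class `modification_summary`: list with `levels` (one
#'   row per centering level: `level`, `pm`, `or`, `conf_low`, `conf_high`)
#'   and `pct_per_10` (one-row tibble), plus `pollutant` and `ref_temp`.
#' @export
modification_summary <- function(fit, levels = NULL, ref_temp = NULL,
                                 x1 = NULL) {
  stopifnot(inherits(fit, "cold_clogit"))
  levels <- levels %||% stats::setNames(fit$pm_pctl,
                                        c("low", "median", "high"))
  x1 <- x1 %||% fit$cb_spec$temp_pctl[["p1"]]
  if (is.null(ref_temp)) {
    med <- if ("median" %in% names(levels)) levels[["median"]] else
      stats::median(levels)
    grid <- default_grid(fit$cb_spec)
    ref_temp <- find_mmt(cumulative_curve(fit, ref_temp = grid[1],
                                          grid = grid, pm_level = med))
  }
  rows <- purrr::imap(levels, function(p, nm) {
    cur <- cumulative_curve(fit, ref_temp = ref_temp, pm_level = p)
    dplyr::mutate(extreme_cold_or(cur, at = x1), level = nm, pm = p,
                  .before = 1)
  })
  structure(
    list(
      pollutant = fit$pollutant,
      ref_temp = ref_temp,
      levels = dplyr::bind_rows(rows),
      pct_per_10 = pct_change_per_10(fit, x1 = x1, x0 = ref_temp)
    ),
    class = "modification_summary"
  )
}

#' @export
print.modification_summary <- function(x, ...) {
  cat("Extreme-cold OR by", toupper(x$pollutant), "level (ref",
      sprintf("%.1f C):\n", x$ref_temp))
  print(as.data.frame(x$levels[c("level", "pm", "or", "conf_low",
                                 "conf_high")]), row.names = FALSE)
  p <- x$pct_per_10
  cat(sprintf("Percent change per 10 ug/m3: %.1f (%.1f, %.1f)\n",
              p$pct, p$conf_low, p$conf_high))
  invisible(x)
}

#' @describeIn modification_summary Flatten to one row per centering level,
#'   with the percent-change columns repeated.
#' @method tidy modification_summary
#' @param x A `modification_summary`.
#' @param ... Unused.
#' @export
tidy.modification_summary <- function(x, ...) {
  dplyr::mutate(
    x$levels,
    pollutant = x$pollutant, ref_temp = x$ref_temp,
    pct_per_10 = x$pct_per_10$pct,
    pct_conf_low = x$pct_per_10$conf_low,
    pct_conf_high = x$pct_per_10$conf_high
  )
}
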