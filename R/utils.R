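# Internal helpers shared across modules.

# Type-7 (linear interpolation) quantile, the package-wide rule for every
# percentile threshold (P1 temperature, PM centering levels).
pctl <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7, na.rm = TRUE)
}

# Deterministic child seed for a named simulation component, so each
# component draws from its own stream derived from the single config seed.
child_seed <- function(seed, component) {
  offs <- c(weather = 11L, pm = 23L, ozone = 31L, deaths = 47L, labels = 59L)
  if (!component %in% names(offs)) {
    abort(paste0("unknown RNG component '", component, "'"))
  }
  (as.integer(seed) * 1009L + offs[[component]]) %% 2147483647L
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(paste0("`", name, "` must be a single positive number"),
          class = "coldmod_config_error")
  }
  invisible(x)
}

# ISO weekday (1 = Monday ... 7 = Sunday) under the proleptic Gregorian
# calendar used by base Date.
iso_wday <- function(date) {
  w <- as.POSIXlt(date)$wday # 0 = Sunday
  ifelse(w == 0L, 7L, w)
}

month_of <- function(date) as.POSIXlt(date)$mon + 1L
year_of <- function(date) as.POSIXlt(date)$year + 1900L

`%||%` <- rlang::`%||%`
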