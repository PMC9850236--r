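#' Lagged moving average
#'
#' Arithmetic mean of a daily series over a lag window: the value at day `t`
#' averages `x[t - lag_range[2]] ... x[t - lag_range[1]]`. Days whose window
#' reaches before the start of the series, or touches any missing value, are
#' returned as `NA` (strata touching such days are later dropped whole).
#'
#' @param x Numeric series indexed by consecutive days.
#' @param lag_range Integer pair `(L0, L1)`, default `c(0, 12)`.
#' @return Numeric vector the length of `x`.
#' @examples
#' moving_average(0:20)[14] # mean of 0..12 = 6
#' @export
moving_average <- function(x, lag_range = c(0L, 12L)) {
  stopifnot(length(lag_range) == 2L, lag_range[1] >= 0,
            lag_range[2] > lag_range[1])
  n <- length(x)
  width <- lag_range[2] - lag_range[1] + 1L
  if (width > n) {
    warn("lag window longer than series; all values missing")
    return(rep(NA_real_, n))
  }
  lags <- seq.int(lag_range[1], lag_range[2])
  acc <- matrix(NA_real_, n, length(lags))
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l < n) acc[(l + 1L):n, i] <- x[seq_len(n - l)]
  }
  rowMeans(acc)
}

#' Default internal knots for the lag dimension
#'
#' Places the internal knots of the lag basis at equally spaced points on
#' the `log(lag + 1)` scale across the lag range, back-transformed to lag
#' units, so knots are denser at short lags where the lag-response varies
#' fastest. The lag basis carries an intercept (the lag-0 effect must not be
#' constrained to zero), so a `df`-column basis needs `df - 2` internal
#' knots.
#'
#' @param lag_range Integer pair `(L0, L1)`.
#' @param df Lag-dimension degrees of freedom (intercept included), `>= 2`.
#' @return Numeric vector of `df - 2` strictly increasing knots in
#'   `(L0, L1)` (empty for `df = 2`).
#' @export
lag_basis_knots <- function(lag_range = c(0L, 12L), df = 4L) {
  stopifnot(df >= 2)
  if (df == 2L) return(numeric(0))
  lg <- seq(log(lag_range[1] + 1), log(lag_range[2] + 1), length.out = df)
  exp(lg[seq.int(2L, df - 1L)]) - 1
}

#' Crossbasis specification for the temperature exposure-lag surface
#'
#' Resolves every knot of the bidimensional DLNM basis from the observed
#' cold-season temperature series: a natural cubic spline over temperature
#' (`var_df` columns, internal knots at equally spaced temperature quantiles,
#' boundary knots at the observed range) crossed with a natural cubic spline
#' over integer lags (`lag_df` columns, internal knots log-spaced via
#' [lag_basis_knots()]). The resolved object carries the observed temperature
#' percentiles used downstream (extreme-cold threshold, curve grids).
#'
#' @param temp Observed (in-season) daily mean temperatures, degrees C.
#' @param var_df,lag_df Degrees of freedom of the two dimensions
#'   (defaults 3 and 4, giving a 12-column crossbasis).
#' @param lag_range Integer pair, default `c(0, 12)` days.
#' @param var_knots,var_boundary,lag_knots Optional explicit knot overrides
#'   (used by the sensitivity battery).
#' @return An object of class `crossbasis_spec`.
#' @export
crossbasis_spec <- function(temp, var_df = 3L, lag_df = 4L,
                            lag_range = c(0L, 12L),
                            var_knots = NULL, var_boundary = NULL,
                            lag_knots = NULL) {
  stopifnot(lag_range[1] >= 0, lag_range[2] > lag_range[1])
  temp <- temp[is.finite(temp)]
  var_spec <- spline_spec(temp, df = var_df, knots = var_knots,
                          boundary_knots = var_boundary)
  lag_knots <- lag_knots %||% lag_basis_knots(lag_range, lag_df)
  lag_spec <- spline_spec(seq.int(lag_range[1], lag_range[2]), df = lag_df,
                          knots = lag_knots,
                          boundary_knots = as.numeric(lag_range),
                          intercept = TRUE)
  structure(
    list(
      var_spec = var_spec, lag_spec = lag_spec,
      lag_range = as.integer(lag_range),
      temp_range = range(temp),
      temp_pctl = stats::setNames(pctl(temp, c(.01, .50, .99)),
                                  c("p1", "p50", "p99"))
    ),
    class = "crossbasis_spec"
  )
}

# Lag-basis matrix evaluated at the integer lags, (L1 - L0 + 1) x lag_df.
lag_basis_matrix <- function(spec) {
  ns_basis(seq.int(spec$lag_range[1], spec$lag_range[2]), spec$lag_spec)
}

# Column labels follow (j, k) with the temperature index j outer and the lag
# index k inner: column (j - 1) * lag_df + k.
crossbasis_colnames <- function(spec) {
  as.vector(t(outer(seq_len(spec$var_spec$df), seq_len(spec$lag_spec$df),
                    function(j, k) paste0("cb", j, ".", k))))
}

#' Build the temperature crossbasis matrix
#'
#' Row `t`, column `(j, k)` holds `sum_l R_j(temp[t - l]) * C_k(l)` over the
#' lag window, where `R` is the temperature basis and `C` the lag basis: the
#' tensor-product crossbasis of the DLNM. Rows whose lag history is
#' incomplete (start of series or missing values) are `NA` and flagged by the
#' `complete` attribute.
#'
#' @param temp Daily temperature series on consecutive days.
#' @param spec A [crossbasis_spec()].
#' @return Numeric matrix `length(temp)` by `var_df * lag_df` with attributes
#'   `spec` and `complete` (logical row flag); class `crossbasis`.
#' @export
build_crossbasis <- function(temp, spec) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(temp)
  lags <- seq.int(spec$lag_range[1], spec$lag_range[2])
  C <- lag_basis_matrix(spec)
  vx <- spec$var_spec$df
  vl <- spec$lag_spec$df
  cb <- matrix(0, n, vx * vl)
  complete <- rep(TRUE, n)
  for (i in seq_along(lags)) {
    l <- lags[i]
    xlag <- c(rep(NA_real_, l), temp)[seq_len(n)]
    Rl <- ns_basis(xlag, spec$var_spec)
    bad <- !is.finite(xlag)
    complete <- complete & !bad
    Rl[bad, ] <- 0 # keep accumulation finite; rows invalidated below
    # accumulate R_j(x_{t-l}) * C_k(l) into column (j-1)*vl + k
    cb <- cb + Rl[, rep(seq_len(vx), each = vl), drop = FALSE] *
      matrix(rep(C[i, ], vx), n, vx * vl, byrow = TRUE)
  }
  cb[!complete, ] <- NA_real_
  colnames(cb) <- crossbasis_colnames(spec)
  if (!any(complete)) {
    abort("no day has a complete lag history", class = "coldmod_data_error")
  }
  structure(cb, spec = spec, complete = complete, class = "crossbasis")
}
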