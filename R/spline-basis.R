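#' Natural cubic spline specification
#'
#' Resolves the knot layout of a natural cubic spline from data, so the same
#' basis can be evaluated reproducibly at new values (prediction grids,
#' referent days). With `df` degrees of freedom and no intercept the basis has
#' `df` columns and `df - 1` internal knots, placed by default at equally
#' spaced quantiles of `x`; boundary knots sit at the observed range. The
#' spline is linear beyond the boundary knots (the natural constraint).
#'
#' @param x Numeric values the spline will be applied to (used only to place
#'   default knots).
#' @param df Degrees of freedom (number of basis columns), a positive integer.
#' @param knots Optional explicit internal knots (data units); overrides the
#'   quantile rule.
#' @param boundary_knots Optional length-2 vector; defaults to `range(x)`.
#' @param intercept Include a constant column (used by the lag dimension of
#'   the crossbasis, where the lag-0 effect must not be constrained to
#'   zero); `df` counts the intercept when present, so the basis always has
#'   `df` columns and `df - 1 - intercept` internal knots.
#' @return An object of class `spline_spec`: a list with `df`, `knots`,
#'   `boundary_knots`, `intercept`.
#' @examples
#' sp <- spline_spec(rnorm(100), df = 3)
#' head(ns_basis(seq(-2, 2, 0.5), sp))
#' @export
spline_spec <- function(x, df, knots = NULL, boundary_knots = NULL,
                        intercept = FALSE) {
  if (!is.numeric(df) || length(df) != 1L || df < 1 || df != round(df)) {
    abort("`df` must be a positive integer", class = "coldmod_spec_error")
  }
  df <- as.integer(df)
  n_knots <- df - 1L - as.integer(intercept)
  if (n_knots < 0L) {
    abort("df too small for an intercept basis", class = "coldmod_spec_error")
  }
  x <- x[is.finite(x)]
  if (is.null(boundary_knots) && length(x) < 2L) {
    abort("need at least two finite values to resolve boundary knots",
          class = "coldmod_data_error")
  }
  boundary_knots <- boundary_knots %||% range(x)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0) {
    abort("`boundary_knots` must be an increasing pair",
          class = "coldmod_spec_error")
  }
  if (is.null(knots)) {
    knots <- if (n_knots >= 1L) {
      pctl(x, seq_len(n_knots) / (n_knots + 1L))
    } else {
      numeric(0)
    }
  }
  knots <- sort(as.numeric(knots))
  if (length(knots) != n_knots) {
    abort(
      paste0("number of internal knots must equal df - 1",
             if (intercept) " - 1 (intercept)"),
      class = "coldmod_spec_error"
    )
  }
  if (length(knots) &&
      (min(knots) <= boundary_knots[1] || max(knots) >= boundary_knots[2])) {
    abort("internal knots must lie strictly inside the boundary knots",
          class = "coldmod_spec_error")
  }
  structure(
    list(df = df, knots = knots, boundary_knots = as.numeric(boundary_knots),
         intercept = isTRUE(intercept)),
    class = "spline_spec"
  )
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the `length(x)` by `df` design matrix of the natural cubic spline
#' described by `spec` (no intercept column; stratum constants absorb it in
#' the conditional-logistic fit). Values beyond the boundary knots are
#' extrapolated linearly.
#'
#' @param x Numeric vector of evaluation points; `NA` propagates to `NA` rows.
#' @param spec A [spline_spec()].
#' @return Numeric matrix with `spec$df` columns.
#' @export
ns_basis <- function(x, spec) {
  stopifnot(inherits(spec, "spline_spec"))
  out <- matrix(NA_real_, length(x), spec$df)
  ok <- is.finite(x)
  ns_df <- spec$df - as.integer(spec$intercept)
  if (any(ok)) {
    B <- if (ns_df == 0L) {
      matrix(numeric(0), sum(ok), 0L)
    } else if (ns_df == 1L) {
      # no internal knots and one column: a single curvature-free (hence
      # linear) function of x
      splines::ns(x[ok], Boundary.knots = spec$boundary_knots, df = 1L)
    } else {
      splines::ns(x[ok], knots = spec$knots,
                  Boundary.knots = spec$boundary_knots)
    }
    out[ok, ] <- if (spec$intercept) cbind(1, B) else B
  }
  colnames(out) <- paste0("b", seq_len(spec$df))
  out
}
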