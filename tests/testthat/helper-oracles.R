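# Independent oracles and small fixtures shared across the suite.

# Truncated-power natural cubic spline basis (Hastie-style construction):
# columns {x, d_1(x) - d_{m-1}(x), ...} with
# d_i(x) = [(x - k_i)_+^3 - (x - k_m)_+^3] / (k_m - k_i),
# where k_1..k_m are all knots (boundary included). Spans the natural-spline
# space (linear beyond the boundary knots); used to validate the B-spline
# representation by cross-projection of column spaces.
tp_natural_basis <- function(x, internal_knots, boundary_knots) {
  k <- sort(c(boundary_knots, internal_knots))
  m <- length(k)
  d <- function(i) {
    (pmax(x - k[i], 0)^3 - pmax(x - k[m], 0)^3) / (k[m] - k[i])
  }
  dm1 <- d(m - 1L)
  cols <- lapply(seq_len(m - 2L), function(i) d(i) - dm1)
  cbind(x, do.call(cbind, cols))
}

# Residual of projecting the columns of B onto span(A, intercept).
projection_residual <- function(A, B) {
  A1 <- cbind(1, A)
  fit <- qr(A1)
  max(abs(B - A1 %*% qr.coef(fit, B)))
}

# Direct double-loop crossbasis: row t, column (j,k) accumulated scalar by
# scalar, the stated brute-force oracle for build_crossbasis().
brute_crossbasis <- function(temp, spec) {
  lags <- seq.int(spec$lag_range[1], spec$lag_range[2])
  C <- coldmod::ns_basis(lags, spec$lag_spec)
  vx <- spec$var_spec$df
  vl <- spec$lag_spec$df
  n <- length(temp)
  out <- matrix(NA_real_, n, vx * vl)
  for (t in seq_len(n)) {
    if (t <= max(lags)) next
    acc <- matrix(0, vx, vl)
    for (li in seq_along(lags)) {
      xv <- temp[t - lags[li]]
      R <- drop(coldmod::ns_basis(xv, spec$var_spec))
      for (j in seq_len(vx)) {
        for (kk in seq_len(vl)) {
          acc[j, kk] <- acc[j, kk] + R[j] * C[li, kk]
        }
      }
    }
    out[t, ] <- as.vector(t(acc)) # (j-1)*vl + k ordering
  }
  out
}

# Brute-force conditional-logistic log-likelihood by direct enumeration of
# the stratified multinomial probabilities.
brute_cloglik <- function(design, beta) {
  xcols <- setdiff(names(design)[vapply(design, is.numeric, logical(1))],
                   c("stratum", "is_case", "weight"))
  ll <- 0
  for (s in unique(design$stratum)) {
    d <- design[design$stratum == s, , drop = FALSE]
    eta <- as.matrix(d[xcols]) %*% beta
    w <- d$weight[1]
    ll <- ll + w * (eta[d$is_case == 1L] - log(sum(exp(eta))))
  }
  ll
}

# Tiny hand-made conditional-logistic fixture: `k` strata of 1 case + 3
# referents with a single covariate.
toy_design <- function(x_by_stratum, case_pos = 1L, weights = NULL) {
  k <- length(x_by_stratum)
  weights <- weights %||% rep(1L, k)
  purrr::map_dfr(seq_len(k), function(s) {
    x <- x_by_stratum[[s]]
    tibble::tibble(
      stratum = s,
      is_case = as.integer(seq_along(x) == case_pos),
      weight = weights[s],
      x = x
    )
  })
}

# Minimal synthetic fit object for the effects module: a converged
# `cold_clogit` with prescribed crossbasis/interaction coefficients and
# covariance, bypassing estimation.
fake_fit <- function(cb_spec, beta_cb, gamma = NULL, V = NULL,
                     pm_pctl = c(p10 = 40, p50 = 52, p90 = 70)) {
  p <- length(beta_cb)
  cb_cols <- coldmod:::crossbasis_colnames(cb_spec)
  int_cols <- sub("^cb", "i", cb_cols)
  nm <- c(cb_cols, int_cols)
  beta <- stats::setNames(c(beta_cb, gamma %||% rep(0, p)), nm)
  Vfull <- V %||% matrix(0, 2 * p, 2 * p)
  dimnames(Vfull) <- list(nm, nm)
  structure(
    list(beta = beta, vcov = Vfull, loglik = 0, n_strata = 1L,
         n_weighted_cases = 1L, converged = TRUE, n_iter = 0L,
         aliased = stats::setNames(rep(FALSE, 2 * p), nm),
         col_groups = list(cb = cb_cols, interaction = int_cols),
         cb_spec = cb_spec, rh_spec = NULL, pollutant = "pm1",
         pm_pctl = pm_pctl, drops = NULL),
    class = "cold_clogit"
  )
}
# Small full-pipeline simulation, sized for unit tests.
small_sim <- function(seed = 1, baseline_rate = 30, ...) {
  coldmod::simulate_study(
    coldmod::sim_config(n_seasons = 1L, baseline_rate = baseline_rate,
                        seed = seed, ...)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
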