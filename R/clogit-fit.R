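#' Weighted conditional-logistic fit by Newton-Raphson
#'
#' Maximises the stratified conditional-logistic log-likelihood
#' `sum_s w_s * (eta_case - log sum_{d in s} exp(eta_d))` over the design
#' table's regressors, with one case day per stratum and the stratum's death
#' count as weight (exact for shared region-day exposures). Newton-Raphson
#' from the zero vector with step-halving on any likelihood decrease;
#' convergence on the max-norm of the score. The covariance is the inverse
#' observed information at the optimum (a robust sandwich variant is
#' available). Columns with no within-stratum variation anywhere (aliased
#' with the stratum constants) are detected, dropped from the fit, and
#' reported with `NA` coefficients.
#'
#' @param design A `cold_design` from [build_design()], or any data frame
#'   with `stratum`, `is_case`, `weight` and numeric regressor columns.
#' @param tol Convergence tolerance on the score max-norm (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @param vcov_type `"information"` (default) or `"sandwich"`.
#' @return An object of class `cold_clogit` with elements `beta` (named,
#'   `NA` for aliased columns), `vcov`, `loglik`, `n_strata`,
#'   `n_weighted_cases`, `converged`, `n_iter`, `aliased`, and the design
#'   metadata (`cb_spec`, `rh_spec`, `pollutant`, `col_groups`, `pm_pctl`).
#' @export
conditional_logistic_fit <- function(design, tol = 1e-8, max_iter = 50L,
                                     vcov_type = c("information", "sandwich")) {
  vcov_type <- match.arg(vcov_type)
  col_groups <- attr(design, "col_groups")
  xcols <- if (!is.null(col_groups)) {
    unlist(col_groups, use.names = FALSE)
  } else {
    setdiff(names(design)[vapply(design, is.numeric, logical(1))],
            c("stratum", "is_case", "weight"))
  }
  X <- as.matrix(design[xcols])
  storage.mode(X) <- "double"
  sid <- match(design$stratum, unique(design$stratum))
  y <- design$is_case
  n_strata <- max(sid)
  if (any(tabulate(sid[y == 1L], n_strata) != 1L)) {
    abort("each stratum must contain exactly one case day",
          class = "coldmod_data_error")
  }
  w_s <- design$weight[y == 1L][order(sid[y == 1L])] # per-stratum weight
  w_row <- w_s[sid]

  # aliasing: within-stratum variance below threshold in every stratum
  n_per <- tabulate(sid, n_strata)
  sx <- rowsum(X, sid)
  sx2 <- rowsum(X^2, sid)
  within_var <- sweep(sx2, 1, n_per, "/") - sweep(sx, 1, n_per, "/")^2
  aliased <- apply(within_var, 2, max) < 1e-12
  if (all(aliased)) {
    abort("all covariates are constant within every stratum (fully aliased)",
          class = "coldmod_fit_error")
  }
  Xa <- X[, !aliased, drop = FALSE]
  k <- ncol(Xa)

  loglik_parts <- function(beta) {
    eta <- drop(Xa %*% beta)
    m <- vapply(split(eta, sid), max, 0)
    e <- exp(eta - m[sid])
    S <- rowsum(e, sid)[, 1]
    p <- e / S[sid]
    ll <- sum(w_s * (eta[y == 1L][order(sid[y == 1L])] - (log(S) + m)))
    list(ll = ll, p = p)
  }

  beta <- rep(0, k)
  cur <- loglik_parts(beta)
  converged <- FALSE
  iter <- 0L
  ll_prev <- -Inf
  U <- crossprod(Xa, w_row * (y - cur$p))
  repeat {
    # primary: score max-norm; secondary: likelihood stalled at floating-
    # point resolution (large weighted counts put |loglik| ~ 1e6, where an
    # absolute score norm of 1e-8 is below representable improvement)
    if (max(abs(U)) < tol ||
        (cur$ll - ll_prev < 1e-11 * (1 + abs(cur$ll)) &&
         max(abs(U)) < 1e-4)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_prev <- cur$ll
    iter <- iter + 1L
    A <- crossprod(Xa, Xa * (w_row * cur$p))
    Ms <- rowsum(Xa * cur$p, sid)
    info <- A - crossprod(Ms, Ms * w_s)
    step <- tryCatch(solve(info, U), error = function(e) {
      abort(paste0("singular information matrix; near-aliased columns: ",
                   paste(colnames(Xa)[diag(info) < 1e-10], collapse = ", ")),
            class = "coldmod_fit_error")
    })
    # step-halving: never accept a likelihood decrease
    h <- 1
    repeat {
      cand <- beta + h * drop(step)
      new <- loglik_parts(cand)
      if (new$ll >= cur$ll - 1e-12 || h < 1e-8) break
      h <- h / 2
    }
    beta <- cand
    cur <- new
    U <- crossprod(Xa, w_row * (y - cur$p))
  }
  if (!converged) {
    abort(paste0("Newton-Raphson did not converge in ", max_iter,
                 " iterations; score max-norm ",
                 format(max(abs(U)), digits = 3)),
          class = "coldmod_convergence_error",
          beta = stats::setNames(beta, colnames(Xa)),
          score_norm = max(abs(U)))
  }

  A <- crossprod(Xa, Xa * (w_row * cur$p))
  Ms <- rowsum(Xa * cur$p, sid)
  info <- A - crossprod(Ms, Ms * w_s)
  V <- solve(info)
  if (vcov_type == "sandwich") {
    # per-stratum weighted score contributions
    resid <- w_row * (y - cur$p)
    Us <- rowsum(Xa * resid, sid)
    V <- V %*% crossprod(Us) %*% V
  }
  V <- (V + t(V)) / 2

  p_all <- length(xcols)
  beta_full <- stats::setNames(rep(NA_real_, p_all), xcols)
  beta_full[!aliased] <- beta
  V_full <- matrix(NA_real_, p_all, p_all, dimnames = list(xcols, xcols))
  V_full[!aliased, !aliased] <- V

  structure(
    list(
      beta = beta_full, vcov = V_full, loglik = cur$ll,
      n_strata = n_strata, n_weighted_cases = sum(w_s),
      converged = converged, n_iter = iter,
      aliased = stats::setNames(aliased, xcols),
      col_groups = col_groups,
      cb_spec = attr(design, "cb_spec"),
      rh_spec = attr(design, "rh_spec"),
      pollutant = attr(design, "pollutant"),
      pm_pctl = attr(design, "pm_pctl"),
      drops = attr(design, "drops")
    ),
    class = "cold_clogit"
  )
}

#' @export
print.cold_clogit <- function(x, ...) {
  cat("Conditional logistic fit (", x$n_strata, " strata, ",
      x$n_weighted_cases, " weighted cases)\n", sep = "")
  cat("log-likelihood:", format(x$loglik), " iterations:", x$n_iter, "\n")
  if (any(x$aliased)) {
    cat("aliased columns:", paste(names(x$aliased)[x$aliased],
                                  collapse = ", "), "\n")
  }
  print(round(x$beta, 4))
  invisible(x)
}

#' @describeIn conditional_logistic_fit One row per coefficient with
#'   standard errors and Wald statistics.
#' @method tidy cold_clogit
#' @param x A `cold_clogit` fit.
#' @param ... Unused.
#' @export
tidy.cold_clogit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(se),
    statistic = unname(x$beta / se),
    p.value = 2 * stats::pnorm(-abs(unname(x$beta / se)))
  )
}

#' @describeIn conditional_logistic_fit One-row model summary.
#' @method glance cold_clogit
#' @export
glance.cold_clogit <- function(x, ...) {
  tibble(
    logLik = x$loglik, n_strata = x$n_strata,
    n_weighted_cases = x$n_weighted_cases,
    n_iter = x$n_iter, converged = x$converged,
    n_aliased = sum(x$aliased)
  )
}
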