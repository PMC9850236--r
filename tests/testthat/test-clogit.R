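test_that("MLE matches a 1-D brute-force maximiser on a toy fixture", {
  des <- toy_design(list(c(1, 0, 0, 1), c(0, 1, 1, 0)))
  fit <- conditional_logistic_fit(des)
  brute <- optimise(function(b) brute_cloglik(des, b),
                    c(-10, 10), maximum = TRUE, tol = 1e-10)
  expect_lt(abs(unname(fit$beta["x"]) - brute$maximum), 1e-6)
  expect_lt(abs(fit$loglik - brute$objective), 1e-8)
})

test_that("likelihood equals direct enumeration on small instances", {
  set.seed(21)
  des <- toy_design(replicate(5, rnorm(4), simplify = FALSE),
                    weights = c(1L, 2L, 1L, 3L, 1L))
  fit <- conditional_logistic_fit(des)
  # reported optimum equals the enumerated likelihood at the MLE ...
  expect_equal(fit$loglik, brute_cloglik(des, unname(fit$beta["x"])),
               tolerance = 1e-10)
  # ... and dominates the enumerated likelihood everywhere else
  for (b in c(-2, -1, 0, 0.5, 2)) {
    expect_lte(brute_cloglik(des, b), fit$loglik + 1e-10)
  }
})

test_that("stratum weights equal stratum repetition", {
  set.seed(31)
  xs <- replicate(4, rnorm(5), simplify = FALSE)
  w <- c(3L, 1L, 2L, 2L)
  des_w <- toy_design(xs, weights = w)
  des_rep <- toy_design(rep(xs, w))
  fw <- conditional_logistic_fit(des_w)
  fr <- conditional_logistic_fit(des_rep)
  expect_lt(abs(fw$loglik - fr$loglik), 1e-10)
  expect_lt(max(abs(fw$beta - fr$beta)), 1e-10)
  expect_lt(max(abs(fw$vcov - fr$vcov)), 1e-8)
})

test_that("covariates constant within every stratum are aliased", {
  des <- toy_design(list(rep(2, 4), rep(-1, 4)))
  expect_error(conditional_logistic_fit(des), class = "coldmod_fit_error")
  # mixed case: constant column dropped, varying column fitted
  des$z <- rnorm(nrow(des))
  des <- des[, c("stratum", "is_case", "weight", "x", "z")]
  fit <- conditional_logistic_fit(des)
  expect_true(fit$aliased[["x"]])
  expect_false(fit$aliased[["z"]])
  expect_true(is.na(fit$beta[["x"]]))
  expect_false(is.na(fit$beta[["z"]]))
})

test_that("stratum-constant shifts leave the fit invariant", {
  set.seed(51)
  xs <- replicate(6, rnorm(4), simplify = FALSE)
  des <- toy_design(xs)
  fit <- conditional_logistic_fit(des)
  shifted <- des
  shifted$x <- shifted$x + 100 * shifted$stratum # constant within stratum
  fit2 <- conditional_logistic_fit(shifted)
  expect_lt(max(abs(fit$beta - fit2$beta)), 1e-6)
  expect_lt(abs(fit$loglik - fit2$loglik), 1e-8)
})

test_that("the score vanishes at the optimum and vcov is symmetric PSD", {
  sim <- small_sim(seed = 6)
  des <- build_design(sim$deaths, sim$exposures, pollutant = "pm1")
  fit <- conditional_logistic_fit(des)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$vcov - t(fit$vcov)), na.rm = TRUE), 1e-10)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # numerical score at the optimum
  xcols <- unlist(fit$col_groups)
  X <- as.matrix(des[xcols])
  eta <- drop(X %*% fit$beta[xcols])
  sid <- match(des$stratum, unique(des$stratum))
  p <- exp(eta) / rowsum(exp(eta), sid)[sid, 1]
  U <- crossprod(X, des$weight * (des$is_case - p))
  expect_lt(max(abs(U)), 1e-6)
})

test_that("fit agrees with survival::clogit on expanded strata", {
  skip_if_not_installed("survival")
  library(survival) # clogit's constructed formula needs Surv() attached
  sim <- small_sim(seed = 3, baseline_rate = 2)
  des <- as.data.frame(build_design(sim$deaths, sim$exposures,
                                    pollutant = "pm1"))
  idx <- rep(seq_len(nrow(des)), des$weight)
  reps <- des[idx, ]
  reps$stratum <- paste(reps$stratum,
                        stats::ave(rep(1, nrow(reps)), idx, FUN = seq_along))
  reps$weight <- 1
  fit <- conditional_logistic_fit(reps)
  xc <- names(fit$beta)
  f <- stats::as.formula(
    paste("is_case ~", paste(xc, collapse = "+"),
          "+ survival::strata(stratum)")
  )
  sf <- survival::clogit(f, data = reps, method = "exact")
  expect_lt(max(abs(coef(sf) - fit$beta[names(coef(sf))])), 1e-6)
  expect_equal(unname(sf$loglik[2]), fit$loglik, tolerance = 1e-8)
})

test_that("Wald CIs for a contrast attain near-nominal coverage", {
  # direct multinomial conditional-logistic simulation: 40 strata of 4 days,
  # one covariate, true beta 0.6; case day drawn with prob prop. to exp(eta)
  set.seed(71)
  beta_true <- 0.6
  hits <- 0L
  n_rep <- 200L
  for (r in seq_len(n_rep)) {
    des <- purrr::map_dfr(1:40, function(s) {
      x <- rnorm(4)
      pr <- exp(beta_true * x)
      case <- sample(4, 1, prob = pr / sum(pr))
      tibble::tibble(stratum = s, is_case = as.integer(seq_len(4) == case),
                     weight = 1L, x = x)
    })
    fit <- conditional_logistic_fit(des)
    se <- sqrt(fit$vcov["x", "x"])
    ci <- fit$beta[["x"]] + c(-1.96, 1.96) * se
    if (ci[1] <= beta_true && beta_true <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.90)
  expect_lte(hits / n_rep, 0.99)
})
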