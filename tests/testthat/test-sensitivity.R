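test_that("the profiled selection intercept solves the constraint", {
  d <- tiny_meta()
  p <- model_params(0.4, 2.2, 0.1, 0.5, 0.9)
  # closed form at gamma1 = 0
  prof <- solve_gamma0(p, 0, 0.35, d)
  expect_identical(prof$gamma0, qnorm(0.35))
  expect_identical(prof$residual, 0)
  # self-consistency at gamma1 > 0: plugging the root back satisfies Eq-style
  # constraint mean(1/P) = 1/p to high precision
  for (pp in c(0.2, 0.6, 0.9)) {
    prof <- solve_gamma0(p, 1.2, pp, d)
    expect_lt(abs(prof$residual), 1e-8)
    ps <- p_select_given_sizes(d$tp + d$fn, d$tn + d$fp, p, prof$gamma0, 1.2)
    expect_equal(mean(1 / ps), 1 / pp, tolerance = 1e-8)
  }
  # gamma0 grows without bound as p approaches 1
  g_near1 <- solve_gamma0(p, 1.2, 0.999, d)$gamma0
  expect_gt(g_near1, solve_gamma0(p, 1.2, 0.9, d)$gamma0)
  expect_error(solve_gamma0(p, 1.2, 1, d), "unadjusted")
})

test_that("the conditional log-likelihood reduces to the unadjusted one at p = 1", {
  d <- tiny_meta()
  p <- model_params(0.4, 2.2, 0.1, 0.5, 0.9)
  expect_equal(as.numeric(conditional_loglik(p, 0.8, 1, d)),
               sum(study_loglik(p, d)))
  # and is finite, carrying the profiled intercept, for p < 1
  ll <- conditional_loglik(p, 0.8, 0.6, d)
  expect_true(is.finite(as.numeric(ll)))
  expect_true(is.finite(attr(ll, "gamma0")))
  expect_lt(abs(attr(ll, "residual")), 1e-8)
  # exact and approximate versions are close on this moderate-size data
  ll_ex <- conditional_loglik(p, 0.8, 0.6, d, method = "exact")
  expect_equal(as.numeric(ll), as.numeric(ll_ex), tolerance = 0.5)
})

test_that("the conditional objective is locally smooth (finite-difference slope)", {
  d <- tiny_meta()
  p <- model_params(0.4, 2.2, 0.1, 0.5, 0.9)
  f <- function(a) as.numeric(conditional_loglik(
    model_params(0.4, a, 0.1, 0.5, 0.9), 0.8, 0.6, d))
  h <- 1e-4
  slope_c <- (f(2.2 + h) - f(2.2 - h)) / (2 * h)
  slope_f <- (f(2.2 + h) - f(2.2)) / h
  expect_equal(slope_c, slope_f, tolerance = 1e-2)
})

test_that("fit_sensitivity at p = 1 is the unadjusted fit", {
  fit1 <- cd64_fit()
  fitp1 <- fit_sensitivity(cd64_data(), p = 1)
  expect_equal(fitp1$params, fit1$params)
  expect_equal(fitp1$sauc, fit1$sauc)
  expect_true(is.na(fitp1$gamma1))
})

test_that("an adjusted fit satisfies its constraint and lowers the SAUC here", {
  d <- tiny_meta()
  fit <- fit_sensitivity(d, p = 0.5, gamma1_start = 1)
  expect_true(fit$converged)
  ll <- conditional_loglik(fit$params, fit$gamma1, 0.5, d)
  expect_lt(abs(attr(ll, "residual")), 1e-8)
  expect_equal(attr(ll, "gamma0"), fit$gamma0, tolerance = 1e-6)
  expect_equal(as.numeric(ll), fit$loglik, tolerance = 1e-8)
  expect_true(fit$sauc > 0 && fit$sauc < 1)
  expect_true(fit$sauc_ci[1] <= fit$sauc && fit$sauc <= fit$sauc_ci[2])
})

test_that("disease-label reversal mirrors the fit (sens/spec exchange)", {
  d <- tiny_meta()
  fit_a <- fit_sensitivity(d, p = 0.6, c0 = 0, c1 = 1, gamma1_start = 1)
  fit_b <- fit_sensitivity(transpose_meta(d), p = 0.6, c0 = 1, c1 = 0,
                           gamma1_start = 1)
  expect_equal(unname(fit_a$sop["sensitivity"]),
               unname(fit_b$sop["specificity"]), tolerance = 1e-3)
  expect_equal(unname(fit_a$sop["specificity"]),
               unname(fit_b$sop["sensitivity"]), tolerance = 1e-3)
  expect_equal(fit_a$params[["theta"]], -fit_b$params[["theta"]], tolerance = 1e-2)
  expect_equal(fit_a$params[["beta"]], -fit_b$params[["beta"]], tolerance = 1e-2)
  expect_equal(fit_a$loglik, fit_b$loglik, tolerance = 1e-5)
})

test_that("sensitivity_curve fills the grid and is weight-independent at p = 1", {
  d <- tiny_meta()
  cur <- sensitivity_curve(d, p_grid = c(0.5, 1),
                           weights = list(lnDOR = c(1 / 2, 1 / 2), sen = c(0, 1)))
  expect_equal(nrow(cur), 4L)
  expect_equal(cur$weights, c("lnDOR", "lnDOR", "sen", "sen"))
  p1 <- dplyr::filter(cur, p == 1)
  expect_equal(p1$sauc[1], p1$sauc[2])
  expect_equal(p1$theta[1], p1$theta[2])
  expect_true(all(cur$converged))
})
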