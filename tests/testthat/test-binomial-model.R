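test_that("study rates follow the logistic latent-biomarker model", {
  expect_equal(unlist(study_rates(0, 0, 0)), c(tpr = 0.5, fpr = 0.5))
  r <- study_rates(0, 2 * qlogis(0.9), 0)
  expect_equal(r$tpr, 0.9)
  expect_equal(r$fpr, 0.1)
  # raising the accuracy deviation raises TPR and lowers FPR
  a_s <- seq(-2, 2, by = 0.5)
  r <- study_rates(0.3, 1.5, 0.2, theta_s = 0.1, alpha_s = a_s)
  expect_true(all(diff(r$tpr) > 0))
  expect_true(all(diff(r$fpr) < 0))
  expect_true(all(r$tpr > 0 & r$tpr < 1 & r$fpr > 0 & r$fpr < 1))
})

test_that("solve_location_scale inverts the summary operating point", {
  expect_equal(unname(solve_location_scale(0.5, 0.5, 0.7)), c(0, 0))
  # closed form against a 2-D numerical root-finder oracle
  oracle <- function(sens, spec, beta) {
    obj <- function(x) {
      s <- sop(x[1], x[2], beta)
      (s["sensitivity"] - sens)^2 + (s["specificity"] - spec)^2
    }
    optim(c(0, 1), obj, method = "BFGS",
          control = list(reltol = 1e-14))$par
  }
  ta <- solve_location_scale(0.9, 0.5, 0.15)
  expect_equal(unname(ta), oracle(0.9, 0.5, 0.15), tolerance = 1e-5)
  # round trip over a grid
  for (se in c(0.6, 0.8, 0.95)) for (sp in c(0.5, 0.8, 0.9)) for (b in c(-0.3, 0, 0.15)) {
    ta <- solve_location_scale(se, sp, b)
    s <- sop(ta[["theta"]], ta[["alpha"]], b)
    expect_equal(unname(s), c(se, sp), tolerance = 1e-12)
  }
  expect_error(solve_location_scale(1, 0.5, 0), "inside")
})

test_that("the quadrature rule integrates a normal density to one", {
  r <- quad_rule(21)
  expect_true(all(r$weights > 0))
  val <- sum(r$weights * exp(r$nodes^2) * dnorm(sqrt(2) * r$nodes)) * sqrt(2)
  expect_equal(val, 1, tolerance = 1e-8)
  expect_error(quad_rule(3), ">= 5")
})

test_that("study_loglik reduces to the fixed-effect binomial when sigmas vanish", {
  d <- tibble::tibble(tp = 7, fp = 3, fn = 3, tn = 17)
  p <- model_params(0.4, 1.2, 0.1, 0, 0)
  r <- study_rates(0.4, 1.2, 0.1)
  expect_equal(
    study_loglik(p, d),
    dbinom(7, 10, r$tpr, log = TRUE) + dbinom(3, 20, r$fpr, log = TRUE),
    tolerance = 1e-8)
})

test_that("per-study outcome probabilities sum to one over the outcome grid", {
  p <- model_params(0.3, 1.1, 0.15, 0.5, 0.8)
  for (n1 in 2:4) for (n0 in 2:4) {
    grid <- expand.grid(tp = 0:n1, fp = 0:n0)
    d <- tibble::tibble(tp = grid$tp, fp = grid$fp,
                        fn = n1 - grid$tp, tn = n0 - grid$fp)
    expect_equal(sum(exp(study_loglik(p, d))), 1, tolerance = 1e-6)
  }
})

test_that("the adaptive quadrature is stable under node doubling", {
  p <- model_params(-0.2, 3.6, 0.1, 0.6, 1.4)
  ll20 <- sum(study_loglik(p, cd64_data(), rule = quad_rule(20)))
  ll40 <- sum(study_loglik(p, cd64_data(), rule = quad_rule(40)))
  expect_lt(abs(ll20 - ll40), 1e-6)
})

test_that("the unadjusted fit is stable across starting points", {
  fit <- cd64_fit()
  expect_true(fit$converged)
  alt_start <- model_params(0, 3, 0, 0.4, 1)
  fit2 <- fit_unadjusted(cd64_data(), start = alt_start)
  expect_lt(abs(fit$loglik - fit2$loglik), 1e-4)
  expect_equal(fit2$params, fit$params, tolerance = 1e-2)
  # the optimum beats the moment start
  start_ll <- sum(study_loglik(fit$diagnostics$start, cd64_data()))
  expect_gte(fit$loglik, start_ll)
})

test_that("tidy and glance summarise fits in broom style", {
  fit <- cd64_fit()
  td <- tidy(fit)
  expect_equal(td$term[1:5],
               c("theta", "alpha", "beta", "sigma_theta", "sigma_alpha"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
  expect_lt(gl$sauc_lower, gl$sauc)
  expect_gt(gl$sauc_upper, gl$sauc)
})
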