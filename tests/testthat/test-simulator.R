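test_that("scenarios encode the design grid with correct true SAUCs", {
  s1 <- make_scenario(1)
  expect_equal(c(s1$sens, s1$spec), c(0.9, 0.5))
  expect_equal(unname(s1$params[c("sigma_theta", "sigma_alpha")]), c(0.6, 1.2))
  expect_equal(s1$params[["beta"]], 0.15)
  expect_equal(s1$true_sauc, 0.832, tolerance = 5e-4)
  expect_equal(make_scenario(2)$true_sauc, 0.798, tolerance = 5e-4)
  expect_equal(make_scenario(3)$true_sauc, 0.869, tolerance = 5e-4)
  s4 <- make_scenario(4)
  expect_equal(c(s4$sens, s4$spec), c(0.9, 0.5))
  expect_equal(unname(s4$params[c("sigma_theta", "sigma_alpha")]), c(1.2, 0.6))
  expect_equal(s4$true_sauc, s1$true_sauc)
  # swapped SD assignment
  s1s <- make_scenario(1, sigma_swap = TRUE)
  expect_equal(unname(s1s$params[c("sigma_theta", "sigma_alpha")]), c(1.2, 0.6))
  expect_error(make_scenario(7), "1..6")
  # the derived (theta, alpha) reproduce the accuracy targets
  s <- sop(s1$params[["theta"]], s1$params[["alpha"]], s1$params[["beta"]])
  expect_equal(unname(s), c(0.9, 0.5), tolerance = 1e-12)
})

test_that("simulation is reproducible and respects the design ranges", {
  scn <- make_scenario(1, S_total = 20)
  a <- simulate_meta(scn, 42)
  b <- simulate_meta(scn, 42)
  expect_identical(a$full, b$full)
  expect_identical(a$published_flags, b$published_flags)
  expect_false(identical(simulate_meta(scn, 43)$full, a$full))
  n1 <- a$full$tp + a$full$fn
  n0 <- a$full$tn + a$full$fp
  expect_true(all(n1 >= 10 & n1 <= 30))
  expect_true(all(n0 >= 200 & n0 <= 300))
  expect_equal(nrow(a$published), sum(a$published_flags))
})

test_that("the design calibration hits the target publication probability", {
  scn <- make_scenario(1, S_total = 15)
  sim <- simulate_meta(scn, 7)
  n1 <- sim$full$tp + sim$full$fn
  n0 <- sim$full$tn + sim$full$fp
  # self-consistency of the root
  ps <- p_select_given_sizes(n1, n0, scn$params, sim$gamma0, scn$gamma1)
  expect_equal(mean(ps), 0.7, tolerance = 1e-8)
  # closed form when the slope vanishes
  expect_equal(calibrate_gamma0_sim(n1, n0, scn$params, 0, 0.4), qnorm(0.4))
  expect_warning(calibrate_gamma0_sim(n1, n0, scn$params, 1.5, 1), "limit")
})

test_that("published fractions concentrate around the target", {
  scn <- make_scenario(1, S_total = 15)
  fr <- vapply(1:300, function(r) mean(simulate_meta(scn, 1000 + r)$published_flags),
               numeric(1))
  mc_se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.7), 3 * mc_se + 0.01)
})

test_that("a no-heterogeneity variant obeys the law of large numbers", {
  scn <- make_scenario(1, S_total = 400)
  scn$params[["sigma_theta"]] <- 0
  scn$params[["sigma_alpha"]] <- 0
  sim <- simulate_meta(scn, 11)
  n1 <- sim$full$tp + sim$full$fn
  expect_equal(mean(sim$full$tp / n1), 0.9, tolerance = 0.02)
  expect_equal(mean(sim$full$fp / (sim$full$tn + sim$full$fp)), 0.5,
               tolerance = 0.02)
})

test_that("sparsity summaries nest and detect saturated tables", {
  dense <- tibble::tibble(tp = c(10, 12), fp = c(8, 9), fn = c(7, 6),
                          tn = c(20, 30))
  expect_equal(unlist(sparsity_summary(dense)),
               c(rate_zero = 0, rate_le3 = 0, rate_le5 = 0))
  scn <- make_scenario(1, S_total = 50)
  for (r in 1:10) {
    sm <- unlist(sparsity_summary(simulate_meta(scn, 50 + r)$full))
    expect_true(sm["rate_zero"] <= sm["rate_le3"] &&
                  sm["rate_le3"] <= sm["rate_le5"])
  }
})

test_that("the study driver is deterministic given its seed", {
  scn <- make_scenario(1, S_total = 15)
  s1 <- run_simulation_study(scn, n_reps = 3, methods = "naive", seed = 5)
  s2 <- run_simulation_study(scn, n_reps = 3, methods = "naive", seed = 5)
  expect_equal(s1, s2)
  expect_true(all(c("sauc_mean", "sauc_sd", "n_converged") %in% names(s1)))
  tr <- attr(s1, "truth")
  expect_equal(unname(tr["sauc"]), make_scenario(1)$true_sauc)
})
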