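test_that("the t-statistic matches direct arithmetic, with continuity correction", {
  # balanced sensitivity: logit(sen) = 0
  d <- tibble::tibble(tp = 9, fn = 9, fp = 4, tn = 30)
  expect_equal(t_statistic(d, 0, 1)$value, 0)
  # zero-cell study: all four cells shifted by 0.5 before computing
  d7 <- tibble::tibble(tp = 17, fp = 0, fn = 7, tn = 12)
  tt <- t_statistic(d7, 1 / 2, 1 / 2)
  expect_true(tt$corrected)
  num <- 0.5 * log(12.5 / 0.5) + 0.5 * log(17.5 / 7.5)
  den <- sqrt(0.25 * (1 / 12.5 + 1 / 0.5) + 0.25 * (1 / 17.5 + 1 / 7.5))
  expect_equal(tt$value, num / den, tolerance = 1e-12)
  # no correction when all cells are positive
  expect_false(t_statistic(tiny_meta(), 1, 0)$corrected[1])
})

test_that("the t-statistic is invariant to joint rescaling of the weights", {
  d <- tiny_meta()
  expect_equal(t_statistic(d, 1 / 2, 1 / 2)$value,
               t_statistic(d, 1 / sqrt(2), 1 / sqrt(2))$value)
  expect_equal(t_statistic(d, 0.3, 0.7)$value,
               t_statistic(d, 0.6, 1.4)$value)
  expect_error(t_statistic(d, 0, 0), "both zero")
})

test_that("the two statistic variants coincide exactly for equal weights", {
  d <- dplyr::bind_rows(tiny_meta(), cd64_data()[, c("tp", "fp", "fn", "tn")])
  expect_equal(t_statistic(d, 1 / 2, 1 / 2, variant = "logit")$value,
               t_statistic(d, 1 / 2, 1 / 2, variant = "eq7")$value,
               tolerance = 1e-12)
  # but differ for one-sided weights
  expect_false(isTRUE(all.equal(
    t_statistic(d, 1, 0, variant = "logit")$value,
    t_statistic(d, 1, 0, variant = "eq7")$value)))
})

test_that("the probit selection function behaves as specified", {
  expect_equal(select_prob_study(c(-3, 0, 5), 0.3, 0), rep(pnorm(0.3), 3))
  expect_equal(select_prob_study(0, 0, 1.2), 0.5)
  t_grid <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(select_prob_study(t_grid, -0.5, 0.8)) > 0))
})

test_that("the exact marginal selection probability matches hand enumeration", {
  p <- model_params(0.2, 1.4, 0.1, 0.4, 0.7)
  # gamma1 = 0: the pmf sums out and only Phi(gamma0) remains
  expect_equal(p_select_given_sizes_exact(6, 9, p, -0.7, 0), pnorm(-0.7),
               tolerance = 1e-10)
  # independent 9-term enumeration at n1 = n0 = 2 (fixed effects for clarity)
  pf <- model_params(0.2, 1.4, 0.1, 0, 0)
  r <- study_rates(0.2, 1.4, 0.1)
  hand <- 0
  for (m11 in 0:2) for (m00 in 0:2) {
    tp <- m11; fn <- 2 - m11; tn <- m00; fp <- 2 - m00
    cells <- c(tp, fp, fn, tn)
    if (any(cells == 0)) cells <- cells + 0.5
    tt <- (0.5 * log(cells[4] / cells[2]) + 0.5 * log(cells[1] / cells[3])) /
      sqrt(0.25 * (1 / cells[4] + 1 / cells[2]) + 0.25 * (1 / cells[1] + 1 / cells[3]))
    hand <- hand + pnorm(-0.4 + 1.1 * tt) *
      dbinom(m11, 2, r$tpr) * dbinom(2 - m00, 2, r$fpr)
  }
  expect_equal(p_select_given_sizes_exact(2, 2, pf, -0.4, 1.1), hand,
               tolerance = 1e-8)
  # probit limits
  expect_gt(p_select_given_sizes_exact(5, 5, p, 12, 1), 1 - 1e-6)
  expect_lt(p_select_given_sizes_exact(5, 5, p, -12, 1), 1e-6)
})

test_that("the asymptotic approximation agrees with the exact oracle and is monotone", {
  p <- model_params(1.184, 2.368, 0.15, 0.6, 1.2)
  expect_equal(p_select_given_sizes(20, 250, p, -0.9, 0), pnorm(-0.9),
               tolerance = 1e-12)
  # monotone non-decreasing in gamma0
  g0s <- seq(-4, 3, by = 0.5)
  ps <- vapply(g0s, function(g) p_select_given_sizes(20, 250, p, g, 1.5),
               numeric(1))
  expect_true(all(diff(ps) > 0))
  # scale invariance in the weights for both versions
  expect_equal(p_select_given_sizes(15, 120, p, -1, 1.2, c0 = 0.5, c1 = 0.5),
               p_select_given_sizes(15, 120, p, -1, 1.2, c0 = 2, c1 = 2),
               tolerance = 1e-12)
  expect_equal(p_select_given_sizes_exact(8, 10, p, -1, 1.2, c0 = 0.3, c1 = 0.7),
               p_select_given_sizes_exact(8, 10, p, -1, 1.2, c0 = 0.6, c1 = 1.4),
               tolerance = 1e-12)
  # approximation error shrinks as both margins grow
  err <- vapply(list(c(10, 50), c(20, 100), c(50, 250)), function(nn) {
    abs(p_select_given_sizes(nn[1], nn[2], p, -2, 1.5) -
          p_select_given_sizes_exact(nn[1], nn[2], p, -2, 1.5))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.02)
})
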