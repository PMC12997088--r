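#' Per-study selection t-statistic
#'
#' The key statistic of the Copas-type selection function is the linear
#' combination `c0 * logit(specificity) + c1 * logit(sensitivity)` of the
#' observed study, studentised by its estimated standard error:
#' \deqn{t = \frac{c_0\log(tn/fp) + c_1\log(tp/fn)}
#'              {\sqrt{c_0^2(1/tn+1/fp) + c_1^2(1/tp+1/fn)}}.}
#' `(c0, c1) = (1/2, 1/2)` gives the t-statistic of the log diagnostic odds
#' ratio, `(0, 1)` of sensitivity alone, `(1, 0)` of specificity alone. The
#' statistic is invariant to joint positive rescaling of `(c0, c1)`. If any
#' cell of a study is zero, 0.5 is added to all four cells of that study
#' first (continuity correction); this correction is used only here, never in
#' the exact likelihood.
#'
#' @param data A data frame of studies (columns `tp`, `fp`, `fn`, `tn`).
#' @param c0,c1 Non-negative weights on logit-specificity and
#'   logit-sensitivity; not both zero.
#' @param variant `"logit"` (default) builds the statistic from
#'   logit-specificity and logit-sensitivity as above. `"eq7"` is an audit
#'   variant pairing TN with FN and TP with FP in the numerator
#'   (`c0 log(tn/fn) + c1 log(tp/fp)`) with the matching variance; the two
#'   coincide whenever `c0 = c1`.
#' @param correction Continuity-correction constant added to all four cells
#'   of a study containing a zero (default 0.5).
#' @return A tibble with columns `value`, `corrected`, `c0`, `c1`, one row
#'   per study.
#' @examples
#' d <- tibble::tibble(tp = 17, fp = 0, fn = 7, tn = 12)
#' t_statistic(d, 1 / 2, 1 / 2)
#' @export
t_statistic <- function(data, c0, c1, variant = c("logit", "eq7"),
                        correction = 0.5) {
  variant <- match.arg(variant)
  if (c0 < 0 || c1 < 0 || (c0 == 0 && c1 == 0)) {
    abort("`c0` and `c1` must be non-negative and not both zero.")
  }
  cc <- .meta_counts(data)
  zero <- cc$tp == 0 | cc$fp == 0 | cc$fn == 0 | cc$tn == 0
  add <- ifelse(zero, correction, 0)
  tp <- cc$tp + add; fp <- cc$fp + add; fn <- cc$fn + add; tn <- cc$tn + add
  if (variant == "logit") {
    num <- c0 * log(tn / fp) + c1 * log(tp / fn)
    den <- sqrt(c0^2 * (1 / tn + 1 / fp) + c1^2 * (1 / tp + 1 / fn))
  } else {
    num <- c0 * log(tn / fn) + c1 * log(tp / fp)
    den <- sqrt(c0^2 * (1 / fn + 1 / tn) + c1^2 * (1 / tp + 1 / fp))
  }
  tibble(value = num / den, corrected = zero, c0 = c0, c1 = c1)
}

# internal: t values only, from raw count vectors
.t_values <- function(tp, fp, fn, tn, c0, c1, correction = 0.5) {
  zero <- tp == 0 | fp == 0 | fn == 0 | tn == 0
  add <- ifelse(zero, correction, 0)
  tp <- tp + add; fp <- fp + add; fn <- fn + add; tn <- tn + add
  (c0 * log(tn / fp) + c1 * log(tp / fn)) /
    sqrt(c0^2 * (1 / tn + 1 / fp) + c1^2 * (1 / tp + 1 / fn))
}

#' Probability a study is published given its t-statistic
#'
#' The probit selection function `Phi(gamma0 + gamma1 * t)`: non-decreasing in
#' `t` when `gamma1 >= 0`, so (for positive weights) studies with more
#' significant accuracy are more likely to be published.
#'
#' @param t t-statistic value(s) (e.g. `t_statistic(...)$value`).
#' @param gamma0 Selection intercept.
#' @param gamma1 Selection slope.
#' @return Selection probabilities in (0, 1).
#' @export
select_prob_study <- function(t, gamma0, gamma1) {
  pnorm(gamma0 + gamma1 * t)
}

# ---- marginal selection probability given study sizes ----------------------

# Ratio mu_U / sigma_U of the key statistic's asymptotic mean to its standard
# error, on the grid of prior quadrature nodes. Returns an S x K matrix for
# size pairs (n1, n0) (vectors of length S) and the K tensor nodes of `rule`.
.t_ratio_grid <- function(par, n1, n0, c0, c1, rule) {
  p <- .check_params(par)
  e1 <- exp(-p[3] / 2); e0 <- exp(p[3] / 2)
  s_th <- p[4]; s_al <- p[5]
  u1 <- sqrt(2) * s_th * rule$z1      # theta_s at prior nodes (length K)
  u2 <- sqrt(2) * s_al * rule$z2
  eta1 <- (p[1] + u1 + (p[2] + u2) / 2) * e1
  eta0 <- (p[1] + u1 - (p[2] + u2) / 2) * e0
  pi1 <- plogis(eta1)                  # length K
  spe <- plogis(-eta0)
  l1 <- pmin(pmax(eta1, -36), 36)      # logit(pi1), capped
  l0 <- pmin(pmax(-eta0, -36), 36)     # logit(spe), capped
  v1 <- pmax(pi1 * (1 - pi1), exp(-36))
  v0 <- pmax(spe * (1 - spe), exp(-36))
  mu <- c0 * l0 + c1 * l1              # length K
  # sigma_U^2 = c0^2/(n0 v0) + c1^2/(n1 v1): S x K
  s2 <- outer(1 / n0, c0^2 / v0) + outer(1 / n1, c1^2 / v1)
  sweep(s2^(-0.5), 2, mu, `*`)
}

# P(select | n1, n0) from a precomputed ratio grid (S x K)
.p_select_from_grid <- function(ratio, gamma0, gamma1, rule) {
  z <- (gamma0 + gamma1 * ratio) / sqrt(1 + gamma1^2)
  w <- exp(rule$logw_prior)
  drop(pnorm(z) %*% w)
}

#' Marginal selection probability given study sizes (normal approximation)
#'
#' The probability that a population study with `n1` diseased and `n0`
#' non-diseased subjects is published, before its counts are observed. For
#' each random-effects value the key statistic is approximately normal with
#' mean `mu_U / sigma_U` and unit variance, so the inner expectation of the
#' probit selection function has the closed form
#' `Phi((gamma0 + gamma1 * mu_U / sigma_U) / sqrt(1 + gamma1^2))`; the outer
#' random-effects expectation is evaluated by Gauss--Hermite quadrature
#' against the prior. Continuity correction never enters here.
#'
#' @param n1,n0 Diseased / non-diseased group sizes (vectors allowed,
#'   recycled to common length).
#' @param params Model parameters (see [model_params()]).
#' @param gamma0,gamma1 Selection intercept and slope.
#' @param c0,c1 Selection statistic weights.
#' @param rule Quadrature rule or node count.
#' @return Selection probabilities in (0, 1), one per size pair.
#' @examples
#' p_select_given_sizes(20, 250, model_params(1, 2, 0.15, 0.6, 1.2), -1, 1.5)
#' @export
p_select_given_sizes <- function(n1, n0, params, gamma0, gamma1,
                                 c0 = 1 / 2, c1 = 1 / 2, rule = quad_rule(21)) {
  rule <- .as_rule(rule)
  k <- max(length(n1), length(n0))
  n1 <- rep_len(n1, k); n0 <- rep_len(n0, k)
  if (any(n1 < 1 | n0 < 1)) abort("`n1` and `n0` must be >= 1.")
  ratio <- .t_ratio_grid(params, n1, n0, c0, c1, rule)
  .p_select_from_grid(ratio, gamma0, gamma1, rule)
}

#' Marginal selection probability given study sizes (exact double sum)
#'
#' Exact evaluation of the marginal selection probability by summing the
#' probit selection function against the joint probability mass function of
#' (TP, TN) marginalised over the random effects:
#' \deqn{P(select \mid n_1, n_0) = \sum_{m_{11}=0}^{n_1}\sum_{m_{00}=0}^{n_0}
#'   \Phi\{\gamma_0+\gamma_1 \tilde t(m_{11}, m_{00})\}\,
#'   P(TP=m_{11}, TN=m_{00} \mid n_1, n_0).}
#' The statistic on hypothetical tables uses the same continuity-correction
#' policy as [t_statistic()]. Cost grows as `n1 * n0`; intended for moderate
#' sizes and as the oracle against which the normal approximation of
#' [p_select_given_sizes()] is validated.
#'
#' @inheritParams p_select_given_sizes
#' @param correction Continuity-correction constant for zero-cell tables.
#' @return A single selection probability in (0, 1).
#' @export
p_select_given_sizes_exact <- function(n1, n0, params, gamma0, gamma1,
                                       c0 = 1 / 2, c1 = 1 / 2,
                                       rule = quad_rule(21), correction = 0.5) {
  rule <- .as_rule(rule)
  stopifnot(length(n1) == 1L, length(n0) == 1L, n1 >= 1, n0 >= 1)
  p <- .check_params(params)
  e1 <- exp(-p[3] / 2); e0 <- exp(p[3] / 2)
  s_th <- p[4]; s_al <- p[5]
  u1 <- sqrt(2) * s_th * rule$z1
  u2 <- sqrt(2) * s_al * rule$z2
  pi1 <- plogis((p[1] + u1 + (p[2] + u2) / 2) * e1)
  pi0 <- plogis((p[1] + u1 - (p[2] + u2) / 2) * e0)
  w <- exp(rule$logw_prior)
  m11 <- 0:n1
  m00 <- 0:n0
  # joint pmf of (TP = m11, TN = m00), marginal over random effects
  pmf <- matrix(0, n1 + 1, n0 + 1)
  for (k in seq_along(w)) {
    pmf <- pmf + w[k] * outer(dbinom(m11, n1, pi1[k]), dbinom(n0 - m00, n0, pi0[k]))
  }
  tt <- outer(m11, m00, function(a, b) {
    .t_values(tp = a, fp = n0 - b, fn = n1 - a, tn = b, c0 = c0, c1 = c1,
              correction = correction)
  })
  sum(pnorm(gamma0 + gamma1 * tt) * pmf)
}

# ---- exact marginal selection probability, reusable across gamma values ----

# Per-size-pair bin structure over the (m11, m00) grid of the t-tilde matrix.
# The t values are fixed by (n1, n0, c0, c1); only the pmf depends on the
# model parameters, so the heavy outer-product work factors into one BLAS
# product per parameter value while the gamma0 root search only touches the
# binned representation.
.exact_sel_structure <- function(n1, n0, c0, c1, n_bins = 400,
                                 correction = 0.5) {
  tt <- outer(0:n1, 0:n0, function(a, b)
    .t_values(tp = a, fp = n0 - b, fn = n1 - a, tn = b, c0 = c0, c1 = c1,
              correction = correction))
  tv <- as.vector(tt)
  br <- seq(min(tv) - 1e-9, max(tv) + 1e-9, length.out = n_bins + 1)
  list(n1 = n1, n0 = n0, tv = tv,
       bidx = findInterval(tv, br, rightmost.closed = TRUE))
}

# Binned t-tilde distributions for every structure, at the given parameters.
# Each bin keeps its probability mass and its mass-weighted mean t value, so
# the binning error is second order in the bin width.
.exact_sel_bins <- function(par, structures, rule) {
  p <- .check_params(par)
  e1 <- exp(-p[3] / 2); e0 <- exp(p[3] / 2)
  u1 <- sqrt(2) * p[4] * rule$z1
  u2 <- sqrt(2) * p[5] * rule$z2
  pi1 <- plogis((p[1] + u1 + (p[2] + u2) / 2) * e1)
  pi0 <- plogis((p[1] + u1 - (p[2] + u2) / 2) * e0)
  w <- exp(rule$logw_prior)
  K <- length(w)
  lapply(structures, function(st) {
    B1 <- matrix(dbinom(rep(0:st$n1, each = K), st$n1, pi1), K)
    B0 <- matrix(dbinom(rep(st$n0 - (0:st$n0), each = K), st$n0, pi0), K)
    pmf <- as.vector(crossprod(B1 * w, B0))
    wb <- rowsum(pmf, st$bidx)
    tb <- rowsum(pmf * st$tv, st$bidx) / pmax(wb, 1e-300)
    list(t = as.vector(tb), w = as.vector(wb))
  })
}

.p_select_from_bins <- function(bins, gamma0, gamma1) {
  vapply(bins, function(b) sum(b$w * pnorm(gamma0 + gamma1 * b$t)), numeric(1))
}
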