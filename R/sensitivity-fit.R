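# ---- profiling the selection intercept -------------------------------------

# Solve mean_s 1/P(select | n1_s, n0_s) = 1/p for gamma0. `p_fun(g0)` returns
# the vector of selection probabilities for the unique size pairs; `idx` maps
# studies to pairs. Monotone: P increases in gamma0, so the left side
# decreases and the root is unique.
.solve_gamma0_fn <- function(p_fun, idx, n_pairs, gamma1, p, bracket = 40) {
  if (gamma1 == 0) {
    g0 <- qnorm(p)
    return(list(gamma0 = g0, residual = 0, bracket = c(-bracket, bracket),
                p_select = rep(pnorm(g0), n_pairs)))
  }
  f <- function(g0) 1 / p - mean(pmin(1 / p_fun(g0)[idx], 1e12))
  flo <- f(-bracket); fhi <- f(bracket)
  if (flo > 0 || fhi < 0) {
    abort(sprintf(
      "Selection-intercept constraint not bracketed in [-%s, %s] (p = %.3g, gamma1 = %.3g).",
      bracket, bracket, p, gamma1))
  }
  root <- uniroot(f, c(-bracket, bracket), f.lower = flo, f.upper = fhi,
                  tol = 1e-12)
  ps <- p_fun(root$root)
  list(gamma0 = root$root,
       residual = mean(1 / ps[idx]) - 1 / p,
       bracket = c(-bracket, bracket),
       p_select = ps)
}

.solve_gamma0_grid <- function(ratio, idx, gamma1, p, rule, bracket = 40) {
  .solve_gamma0_fn(function(g0) .p_select_from_grid(ratio, g0, gamma1, rule),
                   idx, nrow(ratio), gamma1, p, bracket)
}

.size_pairs <- function(cc) {
  key <- paste(cc$n1, cc$n0)
  uk <- !duplicated(key)
  list(n1 = cc$n1[uk], n0 = cc$n0[uk], idx = match(key, key[uk]))
}

#' Profile the selection intercept from the marginal-probability constraint
#'
#' For a fixed marginal selection probability `p`, the selection intercept
#' `gamma0` is determined by the empirical constraint
#' \deqn{\frac1p = \frac1S \sum_s \frac{1}{P(select \mid n_1^{(s)}, n_0^{(s)})},}
#' the observed-study average of inverse marginal selection probabilities.
#' `P(select | n1, n0)` is monotone in `gamma0`, so the root is unique; it is
#' found by safeguarded root search on `[-40, 40]`.
#'
#' @param params Model parameters (see [model_params()]).
#' @param gamma1 Selection slope (fixed).
#' @param p Marginal selection probability, in (0, 1).
#' @param data Data frame of studies; only the margins `n1`, `n0` enter.
#' @param c0,c1 Selection statistic weights.
#' @param rule Quadrature rule or node count.
#' @return A list with `gamma0`, the constraint `residual` at the solution,
#'   the search `bracket`, and `p_select` (per unique size pair).
#' @examples
#' cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
#' solve_gamma0(model_params(0, 3.6, 0, 0.6, 1.4), 1, 0.6, cd64)$gamma0
#' @export
solve_gamma0 <- function(params, gamma1, p, data, c0 = 1 / 2, c1 = 1 / 2,
                         rule = quad_rule(21)) {
  if (p <= 0 || p >= 1) abort("`p` must be in (0, 1); p = 1 is the unadjusted model.")
  rule <- .as_rule(rule)
  cc <- .meta_counts(data)
  sp <- .size_pairs(cc)
  ratio <- .t_ratio_grid(.check_params(params), sp$n1, sp$n0, c0, c1, rule)
  .solve_gamma0_grid(ratio, sp$idx, gamma1, p, rule)
}

# ---- conditional log-likelihood --------------------------------------------

# Internal work-horse: everything data-dependent precomputed in `ctx`.
# `method = "approx"` uses the asymptotic-normal marginal selection
# probability; `method = "exact"` evaluates the double sum over all
# hypothetical tables (binned; feasible for small/medium meta-analyses).
.make_cond_ctx <- function(cc, c0, c1, rule, method = "approx") {
  sp <- .size_pairs(cc)
  structures <- if (method == "exact") {
    purrr::map2(sp$n1, sp$n0, .exact_sel_structure, c0 = c0, c1 = c1)
  }
  list(cc = cc, sp = sp, rule = rule, c0 = c0, c1 = c1, method = method,
       structures = structures,
       t_obs = .t_values(cc$tp, cc$fp, cc$fn, cc$tn, c0, c1))
}

.cond_loglik_ctx <- function(par, gamma1, p, ctx) {
  cc <- ctx$cc; rule <- ctx$rule
  ll_f <- sum(.bb_study_loglik(par, cc$tp, cc$fp, cc$n1, cc$n0, rule))
  p_fun <- if (ctx$method == "exact") {
    bins <- .exact_sel_bins(par, ctx$structures, rule)
    function(g0) .p_select_from_bins(bins, g0, gamma1)
  } else {
    ratio <- .t_ratio_grid(par, ctx$sp$n1, ctx$sp$n0, ctx$c0, ctx$c1, rule)
    function(g0) .p_select_from_grid(ratio, g0, gamma1, rule)
  }
  prof <- .solve_gamma0_fn(p_fun, ctx$sp$idx, length(ctx$sp$n1), gamma1, p)
  sel <- sum(pnorm(prof$gamma0 + gamma1 * ctx$t_obs, log.p = TRUE))
  marg <- sum(log(prof$p_select[ctx$sp$idx]))
  structure(ll_f + sel - marg, gamma0 = prof$gamma0, residual = prof$residual)
}

#' Conditional-on-publication log-likelihood
#'
#' The log-likelihood of the observed (published) studies given that they
#' were published, with the selection intercept `gamma0` profiled out via the
#' marginal-probability constraint at the supplied `p`:
#' \deqn{\ell = \sum_s \log f_P(counts_s) + \sum_s \log\Phi(\gamma_0+\gamma_1 t_s)
#'   - \sum_s \log P(select \mid n_1^{(s)}, n_0^{(s)}),}
#' dropping the parameter-free term involving the size distribution of
#' published studies. `t_s` is the observed-study statistic of
#' [t_statistic()] (continuity-corrected where a cell is zero).
#'
#' @inheritParams solve_gamma0
#' @param data Data frame of studies (full 2x2 counts).
#' @return The log-likelihood value, with attributes `gamma0` (the profiled
#'   intercept) and `residual` (constraint residual).
#' @export
conditional_loglik <- function(params, gamma1, p, data, c0 = 1 / 2, c1 = 1 / 2,
                               rule = quad_rule(21),
                               method = c("approx", "exact")) {
  method <- match.arg(method)
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].")
  rule <- .as_rule(rule)
  cc <- .meta_counts(data)
  par <- .check_params(params)
  if (p == 1) {
    return(structure(sum(.bb_study_loglik(par, cc$tp, cc$fp, cc$n1, cc$n0, rule)),
                     gamma0 = Inf, residual = 0))
  }
  ctx <- .make_cond_ctx(cc, c0, c1, rule, method)
  .cond_loglik_ctx(par, gamma1, p, ctx)
}

# ---- sensitivity fit -------------------------------------------------------

#' Fit the selection-adjusted bivariate binomial SROC model at fixed p
#'
#' Maximises the conditional-on-publication log-likelihood over the five
#' model parameters and the selection slope `gamma1`, with the selection
#' intercept profiled out at every evaluation via the marginal-probability
#' constraint. `p` is the sensitivity parameter: the assumed marginal
#' probability that a population study is published. `p = 1` reduces exactly
#' to [fit_unadjusted()].
#'
#' @param data Data frame of studies.
#' @param p Marginal selection probability, in (0, 1].
#' @param c0,c1 Selection statistic weights (defaults: the lnDOR statistic).
#' @param rule Quadrature rule or node count.
#' @param start Optional start: a named parameter vector, or a `srocpb_fit`
#'   (typically the fit at a neighbouring `p`) whose estimates seed the
#'   optimiser.
#' @param gamma1_start Starting value for the selection slope.
#' @param gamma1_min Lower bound for `gamma1` during estimation. The default
#'   0 restricts selection to favour significant studies; set to `-Inf` to
#'   allow negative slopes.
#' @param gamma1_max Upper bound for `gamma1`. In small meta-analyses the
#'   conditional likelihood can be non-decreasing in `gamma1` indefinitely
#'   (the selection function degenerates towards a step function in t, which
#'   changes the fit less and less); the bound regularises that direction.
#'   Fits pinned at either bound are reported with a diagnostic flag and the
#'   covariance is computed at fixed `gamma1`.
#' @return A `srocpb_fit`. The covariance of the model parameters is the
#'   corresponding block of the inverse observed-information matrix of the
#'   profiled objective over `(theta, alpha, beta, log sigmas, gamma1)`.
#' @examples
#' \donttest{
#' cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
#' fit_sensitivity(cd64, p = 0.6)
#' }
#' @export
fit_sensitivity <- function(data, p, c0 = 1 / 2, c1 = 1 / 2,
                            rule = quad_rule(21), start = NULL,
                            gamma1_start = 0.5, gamma1_min = 0,
                            gamma1_max = 8,
                            method = c("approx", "exact")) {
  method <- match.arg(method)
  if (p <= 0 || p > 1) abort("`p` must be in (0, 1].")
  rule <- .as_rule(rule)
  if (inherits(start, "srocpb_fit")) {
    if (is.finite(start$gamma1)) gamma1_start <- max(start$gamma1, gamma1_min)
    start <- start$params
  }
  if (p == 1) return(fit_unadjusted(data, rule = rule, start = start))
  cc <- .meta_counts(data)
  if (cc$S < 2) warn("Fewer than 2 studies: parameters are not identifiable.")
  ctx <- .make_cond_ctx(cc, c0, c1, rule, method)
  p0 <- if (is.null(start)) .start_values(cc) else .check_params(start)
  x0 <- c(.to_work(p0), min(max(gamma1_start, gamma1_min, 0), gamma1_max))
  nll <- function(x) {
    v <- tryCatch(
      -as.numeric(.cond_loglik_ctx(.from_work(x[1:5]), x[6], p, ctx)),
      error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  opt <- nlminb(x0, nll, lower = c(rep(-Inf, 5), gamma1_min),
                upper = c(rep(Inf, 5), gamma1_max),
                control = list(rel.tol = 1e-9, iter.max = 500, eval.max = 1000))
  p_hat <- .from_work(opt$par[1:5])
  g1_hat <- opt$par[6]
  final <- .cond_loglik_ctx(p_hat, g1_hat, p, ctx)
  g0_hat <- attr(final, "gamma0")
  at_lower <- is.finite(gamma1_min) && g1_hat <= gamma1_min + 1e-6
  at_upper <- is.finite(gamma1_max) && g1_hat >= gamma1_max - 1e-6
  boundary <- at_lower || at_upper
  if (boundary) {
    # selection slope pinned at a bound (at the lower bound the model
    # collapses towards the unadjusted fit; at the upper one the selection
    # function is effectively a step in t): profile covariance at fixed gamma1
    H <- .fd_hessian(function(w) nll(c(w, g1_hat)), opt$par[1:5])
    vcov_work <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 5, 5))
  } else {
    H <- .fd_hessian(nll, opt$par)
    vcov_all <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 6, 6))
    vcov_work <- vcov_all[1:5, 1:5, drop = FALSE]
  }
  vcov <- .vcov_natural(vcov_work, p_hat)
  # nlminb's "false convergence" on a flat profile direction is still a
  # usable optimum when the objective is locally stationary; judge by the
  # achieved gradient via the covariance being well-defined
  ok_code <- opt$convergence == 0 ||
    grepl("relative convergence|x-convergence|false convergence",
          tolower(opt$message %||% ""))
  converged <- ok_code && all(is.finite(vcov))
  .finish_fit(p_hat, vcov, loglik = -opt$objective, cc = cc, rule = rule,
              gamma0 = g0_hat, gamma1 = g1_hat, p = p, c0 = c0, c1 = c1,
              converged = converged,
              diagnostics = list(iterations = opt$iterations,
                                 evaluations = unname(opt$evaluations[1]),
                                 message = opt$message,
                                 constraint_residual = attr(final, "residual"),
                                 gamma1_boundary = boundary,
                                 gamma1_at_upper = at_upper,
                                 start = as.list(p0)))
}

#' Sensitivity analysis over a grid of selection probabilities and mechanisms
#'
#' Runs [fit_sensitivity()] over every combination of marginal selection
#' probability in `p_grid` and selection-statistic weights, warm-starting each
#' fit from the neighbouring larger `p` (the surfaces deform continuously as
#' `p` decreases from 1). The conventional presets are `lnDOR = (1/2, 1/2)`,
#' `sen = (0, 1)` and `spe = (1, 0)`.
#'
#' @param data Data frame of studies.
#' @param p_grid Selection probabilities in (0, 1].
#' @param weights Named list of `c(c0, c1)` pairs.
#' @param rule Quadrature rule or node count.
#' @param keep_fits If `TRUE`, attach the full fit objects as a list column.
#' @return A tibble with one row per (weights, p): parameter estimates,
#'   selection parameters, SOP, SAUC with CI, log-likelihood and convergence.
#'   Failed cells carry `NA` estimates and `converged = FALSE`.
#' @export
sensitivity_curve <- function(data, p_grid = c(0.2, 0.4, 0.6, 0.8, 1),
                              weights = list(lnDOR = c(1 / 2, 1 / 2),
                                             sen = c(0, 1), spe = c(1, 0)),
                              rule = quad_rule(21), keep_fits = FALSE,
                              method = c("approx", "exact")) {
  method <- match.arg(method)
  if (length(p_grid) == 0L) abort("`p_grid` must be non-empty.")
  rule <- .as_rule(rule)
  if (is.null(names(weights))) {
    names(weights) <- vapply(weights, function(w)
      sprintf("c0=%.3g,c1=%.3g", w[1], w[2]), character(1))
  }
  base_fit <- tryCatch(fit_unadjusted(data, rule = rule), error = function(e) NULL)
  rows <- list(); fits <- list()
  for (wn in names(weights)) {
    w <- weights[[wn]]
    p_desc <- sort(unique(p_grid), decreasing = TRUE)
    warm <- base_fit
    cell <- list()
    for (pp in p_desc) {
      fit <- tryCatch(
        fit_sensitivity(data, p = pp, c0 = w[1], c1 = w[2], rule = rule,
                        start = warm, method = method),
        error = function(e) e)
      cell[[as.character(pp)]] <- fit
      if (inherits(fit, "srocpb_fit") && fit$converged) warm <- fit
    }
    for (pp in p_grid) {
      fit <- cell[[as.character(pp)]]
      key <- paste(wn, pp)
      if (inherits(fit, "srocpb_fit")) {
        rows[[key]] <- tibble(
          weights = wn, c0 = w[1], c1 = w[2], p = pp,
          theta = fit$params[["theta"]], alpha = fit$params[["alpha"]],
          beta = fit$params[["beta"]],
          sigma_theta = fit$params[["sigma_theta"]],
          sigma_alpha = fit$params[["sigma_alpha"]],
          gamma0 = fit$gamma0, gamma1 = fit$gamma1,
          sensitivity = unname(fit$sop["sensitivity"]),
          specificity = unname(fit$sop["specificity"]),
          sauc = fit$sauc, sauc_lower = fit$sauc_ci[1],
          sauc_upper = fit$sauc_ci[2],
          loglik = fit$loglik, converged = fit$converged,
          error = NA_character_)
        fits[[key]] <- fit
      } else {
        rows[[key]] <- tibble(
          weights = wn, c0 = w[1], c1 = w[2], p = pp,
          theta = NA_real_, alpha = NA_real_, beta = NA_real_,
          sigma_theta = NA_real_, sigma_alpha = NA_real_,
          gamma0 = NA_real_, gamma1 = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_,
          sauc = NA_real_, sauc_lower = NA_real_, sauc_upper = NA_real_,
          loglik = NA_real_, converged = FALSE,
          error = conditionMessage(fit))
        fits[[key]] <- NULL
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (keep_fits) out$fit <- unname(fits[paste(out$weights, out$p)])
  class(out) <- c("srocpb_curve", class(out))
  out
}
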