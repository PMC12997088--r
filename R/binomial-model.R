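#' Study-level true- and false-positive rates
#'
#' The bivariate binomial SROC model places a logistic-distributed latent
#' biomarker in each disease class. With overall location `theta`, overall
#' accuracy `alpha`, log scale-asymmetry `beta`, and study-level deviations
#' `theta_s`, `alpha_s`, the per-study rates are
#' \deqn{\pi_1 = G\{(\theta+\theta_s+(\alpha+\alpha_s)/2)e^{-\beta/2}\},\quad
#'       \pi_0 = G\{(\theta+\theta_s-(\alpha+\alpha_s)/2)e^{ \beta/2}\},}
#' with `G` the standard logistic c.d.f. The diseased-class predictor is
#' scaled by `exp(-beta/2)` and the non-diseased one by `exp(beta/2)`, the
#' scaling under which the summary ROC curve of [sroc()] is the exact
#' elimination of `theta` from the summary operating point.
#'
#' @param theta,alpha,beta Overall model parameters.
#' @param theta_s,alpha_s Study-level random-effect deviations (default 0).
#' @return A tibble with columns `tpr` and `fpr`, both strictly in (0, 1).
#' @examples
#' study_rates(0, 0, 0)                      # (0.5, 0.5)
#' study_rates(0, 2 * qlogis(0.9), 0)        # tpr 0.9, fpr 0.1
#' @export
study_rates <- function(theta, alpha, beta, theta_s = 0, alpha_s = 0) {
  tpr <- plogis((theta + theta_s + (alpha + alpha_s) / 2) * exp(-beta / 2))
  fpr <- plogis((theta + theta_s - (alpha + alpha_s) / 2) * exp(beta / 2))
  tibble(tpr = tpr, fpr = fpr)
}

#' Summary operating point
#'
#' The overall (sensitivity, specificity) pair implied by the model, i.e. the
#' study-level rates evaluated at zero random effects:
#' sensitivity \eqn{= G\{(\theta+\alpha/2)e^{-\beta/2}\}}, specificity
#' \eqn{= G\{(\alpha/2-\theta)e^{\beta/2}\}}.
#'
#' @param theta,alpha,beta Model parameters, or a single named vector/list
#'   with elements `theta`, `alpha`, `beta` as first argument.
#' @return Named numeric vector `c(sensitivity, specificity)`.
#' @examples
#' sop(0, 0, 0)
#' @export
sop <- function(theta, alpha = NULL, beta = NULL) {
  if (is.null(alpha)) {
    p <- unlist(theta)
    theta <- p[["theta"]]; alpha <- p[["alpha"]]; beta <- p[["beta"]]
  }
  theta <- unname(theta); alpha <- unname(alpha); beta <- unname(beta)
  c(sensitivity = plogis((theta + alpha / 2) * exp(-beta / 2)),
    specificity = plogis((alpha / 2 - theta) * exp(beta / 2)))
}

#' Solve (theta, alpha) from a target summary operating point
#'
#' Closed-form inversion of the summary operating point at fixed `beta`:
#' \deqn{\alpha = \mathrm{logit}(sens)e^{\beta/2} + \mathrm{logit}(spec)e^{-\beta/2},}
#' \deqn{\theta = \{\mathrm{logit}(sens)e^{\beta/2} - \mathrm{logit}(spec)e^{-\beta/2}\}/2.}
#' Used to construct simulation scenarios from target accuracy pairs.
#'
#' @param sens,spec Target overall sensitivity and specificity, in (0, 1).
#' @param beta Log scale-asymmetry parameter.
#' @return Named numeric vector `c(theta, alpha)`; [sop()] at these values
#'   reproduces `(sens, spec)` to machine precision.
#' @examples
#' solve_location_scale(0.9, 0.5, 0.15)
#' @export
solve_location_scale <- function(sens, spec, beta) {
  if (any(sens <= 0 | sens >= 1 | spec <= 0 | spec >= 1)) {
    abort("`sens` and `spec` must be strictly inside (0, 1).")
  }
  a <- qlogis(sens) * exp(beta / 2) + qlogis(spec) * exp(-beta / 2)
  th <- (qlogis(sens) * exp(beta / 2) - qlogis(spec) * exp(-beta / 2)) / 2
  c(theta = th, alpha = a)
}

# ---- parameter packing -----------------------------------------------------

.param_names <- c("theta", "alpha", "beta", "sigma_theta", "sigma_alpha")
.sigma_floor <- 1e-6

.check_params <- function(params) {
  p <- unlist(params)
  if (!all(.param_names %in% names(p))) {
    abort(paste0("`params` must contain: ", paste(.param_names, collapse = ", ")))
  }
  p <- p[.param_names]
  if (any(!is.finite(p))) abort("Non-finite model parameters.")
  if (any(p[c("sigma_theta", "sigma_alpha")] < 0)) {
    abort("sigma_theta and sigma_alpha must be >= 0.")
  }
  p
}

.to_work <- function(p) {
  c(p[1:3], log(pmax(p[4:5], .sigma_floor)))
}
.from_work <- function(w) {
  setNames(c(w[1:3], exp(w[4:5])), .param_names)
}

#' Convenience constructor for a model parameter vector
#'
#' @param theta,alpha,beta Location, accuracy, and log scale-asymmetry.
#' @param sigma_theta,sigma_alpha Random-effect standard deviations (>= 0).
#' @return A named numeric vector in the canonical order.
#' @export
model_params <- function(theta = 0, alpha = 0, beta = 0,
                         sigma_theta = 0, sigma_alpha = 0) {
  .check_params(c(theta = theta, alpha = alpha, beta = beta,
                  sigma_theta = sigma_theta, sigma_alpha = sigma_alpha))
}

# ---- marginal likelihood by adaptive Gauss-Hermite -------------------------

# Vectorised over studies. For each study the integrand
#   g(u) = Binom(tp; n1, pi1(u)) Binom(fp; n0, pi0(u)) phi(u1; s_th) phi(u2; s_al)
# is log-concave in u = (theta_s, alpha_s); its mode is found by Newton with
# analytic gradient/Hessian and the integral evaluated by a Gauss-Hermite rule
# recentred at the mode and rescaled by the Cholesky factor of the negative
# inverse Hessian (adaptive GH). Returns the vector of per-study log
# marginal probabilities.
.bb_study_loglik <- function(par, tp, fp, n1, n0, rule) {
  p <- .check_params(par)
  theta <- p[1]; alpha <- p[2]; beta <- p[3]
  s_th <- max(p[4], .sigma_floor); s_al <- max(p[5], .sigma_floor)
  e1 <- exp(-beta / 2); e0 <- exp(beta / 2)
  S <- length(tp)
  it_th <- 1 / s_th^2; it_al <- 1 / s_al^2

  # Newton iterations for the joint mode, all studies at once
  m1 <- numeric(S); m2 <- numeric(S)
  for (it in 1:60) {
    eta1 <- (theta + m1 + (alpha + m2) / 2) * e1
    eta0 <- (theta + m1 - (alpha + m2) / 2) * e0
    pi1 <- plogis(eta1); pi0 <- plogis(eta0)
    r1 <- tp - n1 * pi1; r0 <- fp - n0 * pi0
    g1 <- r1 * e1 + r0 * e0 - m1 * it_th
    g2 <- r1 * e1 / 2 - r0 * e0 / 2 - m2 * it_al
    v1 <- n1 * pi1 * (1 - pi1); v0 <- n0 * pi0 * (1 - pi0)
    h11 <- -(v1 * e1^2 + v0 * e0^2) - it_th
    h12 <- -(v1 * e1^2 - v0 * e0^2) / 2
    h22 <- -(v1 * e1^2 + v0 * e0^2) / 4 - it_al
    det <- h11 * h22 - h12^2
    d1 <- -( h22 * g1 - h12 * g2) / det
    d2 <- -(-h12 * g1 + h11 * g2) / det
    # damp very large steps (far-from-mode starts with extreme counts)
    nrm <- sqrt(d1^2 + d2^2)
    sc <- ifelse(nrm > 4, 4 / nrm, 1)
    m1 <- m1 + sc * d1
    m2 <- m2 + sc * d2
    if (max(abs(g1), abs(g2)) < 1e-10) break
  }

  # negative Hessian at the mode and its inverse Cholesky factor
  eta1 <- (theta + m1 + (alpha + m2) / 2) * e1
  eta0 <- (theta + m1 - (alpha + m2) / 2) * e0
  pi1 <- plogis(eta1); pi0 <- plogis(eta0)
  v1 <- n1 * pi1 * (1 - pi1); v0 <- n0 * pi0 * (1 - pi0)
  a11 <- (v1 * e1^2 + v0 * e0^2) + it_th
  a12 <- (v1 * e1^2 - v0 * e0^2) / 2
  a22 <- (v1 * e1^2 + v0 * e0^2) / 4 + it_al
  det <- a11 * a22 - a12^2
  s11 <- a22 / det; s12 <- -a12 / det; s22 <- a11 / det
  l11 <- sqrt(s11); l21 <- s12 / l11; l22 <- sqrt(pmax(s22 - l21^2, 1e-300))

  # transformed nodes: u = m + sqrt(2) L z, per study x node
  z1 <- rule$z1; z2 <- rule$z2
  u1 <- m1 + sqrt(2) * outer(l11, z1)
  u2 <- m2 + sqrt(2) * (outer(l21, z1) + outer(l22, z2))
  eta1 <- (theta + u1 + (alpha + u2) / 2) * e1
  eta0 <- (theta + u1 - (alpha + u2) / 2) * e0
  lg <- dbinom(tp, n1, plogis(eta1), log = TRUE) +
    dbinom(fp, n0, plogis(eta0), log = TRUE) +
    dnorm(u1, 0, s_th, log = TRUE) + dnorm(u2, 0, s_al, log = TRUE)
  lg <- sweep(lg, 2, rule$logw, `+`)
  unname(.logsumexp_rows(lg) + log(2) + log(l11 * l22))
}

#' Log marginal likelihood contribution of one or more studies
#'
#' Marginalises the exact binomial within-study model over the two normal
#' random effects by adaptive Gauss--Hermite quadrature. No continuity
#' correction is involved: zero cells are handled exactly by the binomial
#' probability mass function.
#'
#' @param params Model parameters (named vector or list with `theta`, `alpha`,
#'   `beta`, `sigma_theta`, `sigma_alpha`; see [model_params()]).
#' @param data A data frame of studies (see [as_meta()]); may be a single row.
#' @param rule A quadrature rule from [quad_rule()] or the number of nodes.
#' @return Numeric vector of per-study log marginal probabilities.
#' @examples
#' d <- tibble::tibble(tp = 8, fp = 2, fn = 2, tn = 18)
#' study_loglik(model_params(1, 2, 0.1, 0.5, 0.5), d)
#' @export
study_loglik <- function(params, data, rule = quad_rule(21)) {
  rule <- .as_rule(rule)
  cc <- .meta_counts(data)
  .bb_study_loglik(.check_params(params), cc$tp, cc$fp, cc$n1, cc$n0, rule)
}

# moment-based starting values from continuity-corrected empirical logits
.start_values <- function(cc) {
  l1 <- log((cc$tp + 0.5) / (cc$fn + 0.5))
  l0 <- log((cc$tn + 0.5) / (cc$fp + 0.5))
  a0 <- mean(l1) + mean(l0)
  th0 <- (mean(l1) - mean(l0)) / 2
  s_th0 <- min(max(sd((l1 - l0) / 2), 0.1), 2)
  s_al0 <- min(max(sd(l1 + l0), 0.1), 2)
  if (!is.finite(s_th0)) s_th0 <- 0.5
  if (!is.finite(s_al0)) s_al0 <- 0.5
  setNames(c(th0, a0, 0, s_th0, s_al0), .param_names)
}

# central finite-difference Hessian of f at x
.fd_hessian <- function(f, x, h_rel = 1e-4) {
  k <- length(x)
  h <- h_rel * (1 + abs(x))
  H <- matrix(NA_real_, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h[i]
        xm <- x; xm[i] <- x[i] - h[i]
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
      } else {
        xpp <- x; xpp[i] <- x[i] + h[i]; xpp[j] <- x[j] + h[j]
        xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
        xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
        xmm <- x; xmm[i] <- x[i] - h[i]; xmm[j] <- x[j] - h[j]
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) /
          (4 * h[i] * h[j])
      }
    }
  }
  H
}

# map a covariance on the working scale (log sigmas) to the natural scale
.vcov_natural <- function(vcov_work, p_nat) {
  J <- diag(c(1, 1, 1, p_nat[4], p_nat[5]))
  V <- J %*% vcov_work %*% J
  dimnames(V) <- list(.param_names, .param_names)
  V
}

#' Fit the bivariate binomial SROC model with no selection adjustment
#'
#' Maximum likelihood for the five model parameters, integrating the random
#' effects by adaptive Gauss--Hermite quadrature. This is the `p = 1`
#' (no selective publication) analysis; [fit_sensitivity()] generalises it.
#'
#' @param data A data frame of studies (columns `tp`, `fp`, `fn`, `tn`).
#' @param rule Quadrature rule from [quad_rule()], or node count.
#' @param start Optional named starting values; defaults to moment estimates
#'   from continuity-corrected empirical logits.
#' @return A `srocpb_fit` object: parameter estimates, observed-information
#'   covariance, summary operating point, SAUC with logit-scale 95% CI,
#'   log-likelihood, and convergence diagnostics. See [tidy.srocpb_fit()].
#' @examples
#' cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
#' fit <- fit_unadjusted(cd64)
#' fit$sauc
#' @export
fit_unadjusted <- function(data, rule = quad_rule(21), start = NULL) {
  rule <- .as_rule(rule)
  cc <- .meta_counts(data)
  if (cc$S < 2) warn("Fewer than 2 studies: the random-effect SDs are not identifiable.")
  p0 <- if (is.null(start)) .start_values(cc) else .check_params(start)
  w0 <- .to_work(p0)
  nll <- function(w) {
    p <- .from_work(w)
    v <- -sum(.bb_study_loglik(p, cc$tp, cc$fp, cc$n1, cc$n0, rule))
    if (!is.finite(v)) 1e10 else v
  }
  opt <- nlminb(w0, nll, control = list(rel.tol = 1e-10, iter.max = 500, eval.max = 1000))
  p_hat <- .from_work(opt$par)
  H <- .fd_hessian(nll, opt$par)
  vcov_work <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 5, 5))
  vcov <- .vcov_natural(vcov_work, p_hat)
  converged <- opt$convergence == 0 && all(is.finite(vcov))
  .finish_fit(p_hat, vcov, loglik = -opt$objective, cc = cc, rule = rule,
              gamma0 = NA_real_, gamma1 = NA_real_, p = 1,
              c0 = NA_real_, c1 = NA_real_,
              converged = converged,
              diagnostics = list(iterations = opt$iterations,
                                 evaluations = unname(opt$evaluations[1]),
                                 message = opt$message,
                                 start = as.list(p0)))
}

# assemble a srocpb_fit from estimates + covariance
.finish_fit <- function(p_hat, vcov, loglik, cc, rule, gamma0, gamma1, p,
                        c0, c1, converged, diagnostics) {
  sop_hat <- sop(p_hat[1], p_hat[2], p_hat[3])
  sauc_hat <- sauc(p_hat[2], p_hat[3])
  vab <- vcov[c("alpha", "beta"), c("alpha", "beta")]
  ci <- if (all(is.finite(vab))) {
    sauc_ci(p_hat[2], p_hat[3], vab)
  } else {
    c(se = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  new_srocpb_fit(
    params = p_hat, gamma0 = gamma0, gamma1 = gamma1, p = p, c0 = c0, c1 = c1,
    loglik = loglik, vcov = vcov, sop = sop_hat,
    sauc = sauc_hat, sauc_se = unname(ci["se"]),
    sauc_ci = unname(ci[c("lower", "upper")]),
    converged = converged, diagnostics = diagnostics,
    n_studies = cc$S, nodes = rule$n_nodes
  )
}

new_srocpb_fit <- function(params, gamma0, gamma1, p, c0, c1, loglik, vcov,
                           sop, sauc, sauc_se, sauc_ci, converged, diagnostics,
                           n_studies, nodes) {
  structure(
    list(params = params, gamma0 = gamma0, gamma1 = gamma1, p = p,
         c0 = c0, c1 = c1, loglik = loglik, vcov = vcov, sop = sop,
         sauc = sauc, sauc_se = sauc_se, sauc_ci = sauc_ci,
         converged = converged, diagnostics = diagnostics,
         n_studies = n_studies, nodes = nodes),
    class = "srocpb_fit"
  )
}

#' @export
print.srocpb_fit <- function(x, ...) {
  adj <- if (is.finite(x$gamma1)) {
    sprintf("selection-adjusted (p = %.3g, c0 = %.3g, c1 = %.3g)", x$p, x$c0, x$c1)
  } else "no selection adjustment (p = 1)"
  cat("<srocpb_fit> bivariate binomial SROC model,", adj, "\n")
  cat(sprintf("  studies: %d   logLik: %.4f   converged: %s\n",
              x$n_studies, x$loglik, x$converged))
  est <- x$params
  se <- sqrt(pmax(diag(x$vcov), 0))
  for (i in seq_along(est)) {
    cat(sprintf("  %-12s %8.4f  (se %.4f)\n", names(est)[i], est[i], se[i]))
  }
  if (is.finite(x$gamma1)) {
    cat(sprintf("  gamma1       %8.4f   gamma0 %8.4f\n", x$gamma1, x$gamma0))
  }
  cat(sprintf("  SOP: sensitivity %.3f, specificity %.3f\n",
              x$sop["sensitivity"], x$sop["specificity"]))
  cat(sprintf("  SAUC: %.3f  (95%% CI %.3f, %.3f)\n",
              x$sauc, x$sauc_ci[1], x$sauc_ci[2]))
  invisible(x)
}
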