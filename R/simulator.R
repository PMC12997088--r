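#' Construct a simulation scenario for selectively published meta-analyses
#'
#' Six data-generating scenarios cross three overall accuracy pairs,
#' (sens, spec) = (0.9, 0.5), (0.5, 0.9), (0.8, 0.8), with two random-effect
#' SD pairs, (sigma_theta, sigma_alpha) = (0.6, 1.2) for experiments 1-3 and
#' (1.2, 0.6) for experiments 4-6. The scale parameter is beta = 0.15 and
#' (theta, alpha) are recovered from the accuracy pair in closed form. Studies
#' draw n1 ~ U\{10..30\} diseased and n0 ~ U\{200..300\} non-diseased
#' subjects; publication follows a probit selection function on the lnDOR
#' t-statistic with slope `gamma1 = 1.5`, whose intercept is calibrated so the
#' average selection probability equals `p_target`.
#'
#' @param experiment_id Integer 1-6.
#' @param p_target Marginal publication probability the selection intercept
#'   is calibrated to (default 0.7).
#' @param S_total Number of studies generated (published + unpublished).
#' @param gamma1 Selection slope.
#' @param c0,c1 Weights of the true selection statistic (default lnDOR).
#' @param sigma_swap If `TRUE`, swap the SD-pair assignment (experiments 1-3
#'   get (1.2, 0.6) and 4-6 get (0.6, 1.2)).
#' @return A `srocpb_scenario` list: accuracy targets, model parameters,
#'   selection settings, size ranges and the scenario's true SAUC.
#' @examples
#' make_scenario(1)$true_sauc
#' @export
make_scenario <- function(experiment_id, p_target = 0.7, S_total = 15,
                          gamma1 = 1.5, c0 = 1 / 2, c1 = 1 / 2,
                          sigma_swap = FALSE) {
  if (!experiment_id %in% 1:6) abort("`experiment_id` must be in 1..6.")
  acc <- list(c(0.9, 0.5), c(0.5, 0.9), c(0.8, 0.8))[[(experiment_id - 1) %% 3 + 1]]
  first_pair <- experiment_id <= 3
  if (sigma_swap) first_pair <- !first_pair
  sg <- if (first_pair) c(0.6, 1.2) else c(1.2, 0.6)
  beta <- 0.15
  ta <- solve_location_scale(acc[1], acc[2], beta)
  params <- model_params(ta[["theta"]], ta[["alpha"]], beta, sg[1], sg[2])
  structure(
    list(experiment_id = experiment_id, sens = acc[1], spec = acc[2],
         params = params, gamma1 = gamma1, p_target = p_target,
         c0 = c0, c1 = c1, S_total = S_total,
         n1_range = c(10L, 30L), n0_range = c(200L, 300L),
         true_sauc = sauc(ta[["alpha"]], beta)),
    class = "srocpb_scenario"
  )
}

#' @export
print.srocpb_scenario <- function(x, ...) {
  cat(sprintf(
    "<srocpb_scenario> experiment %d: sens %.2f spec %.2f, sigma (%.1f, %.1f)\n",
    x$experiment_id, x$sens, x$spec,
    x$params[["sigma_theta"]], x$params[["sigma_alpha"]]))
  cat(sprintf("  beta %.2f, gamma1 %.2f, p_target %.2f, S_total %d, true SAUC %.3f\n",
              x$params[["beta"]], x$gamma1, x$p_target, x$S_total, x$true_sauc))
  invisible(x)
}

#' Calibrate the selection intercept of a simulation design
#'
#' Finds `gamma0` such that the average marginal selection probability over
#' the generated study sizes equals the target publication probability:
#' `mean(P(select | n1, n0)) = p_target`. Note the design constraint averages
#' the probabilities themselves, whereas the estimation constraint of
#' [solve_gamma0()] averages their inverses over *published* studies.
#'
#' @param n1,n0 Vectors of study sizes (one entry per generated study).
#' @param params Model parameters.
#' @param gamma1 Selection slope.
#' @param p_target Target marginal publication probability in (0, 1).
#' @param c0,c1 Selection statistic weights.
#' @param rule Quadrature rule or node count.
#' @return The calibrated `gamma0` (scalar).
#' @export
calibrate_gamma0_sim <- function(n1, n0, params, gamma1, p_target,
                                 c0 = 1 / 2, c1 = 1 / 2, rule = quad_rule(21)) {
  if (length(n1) == 0L) abort("`n1`/`n0` must be non-empty.")
  rule <- .as_rule(rule)
  if (p_target <= 0) abort("`p_target` must be in (0, 1].")
  if (p_target >= 1) {
    warn("p_target = 1 is attained only in the limit; returning the bracket edge.")
    return(40)
  }
  if (gamma1 == 0) return(qnorm(p_target))
  ratio <- .t_ratio_grid(.check_params(params), n1, n0, c0, c1, rule)
  f <- function(g0) mean(.p_select_from_grid(ratio, g0, gamma1, rule)) - p_target
  flo <- f(-40); fhi <- f(40)
  if (flo > 0 || fhi < 0) abort("Calibration root not bracketed in [-40, 40].")
  uniroot(f, c(-40, 40), f.lower = flo, f.upper = fhi, tol = 1e-12)$root
}

#' Simulate one selectively published meta-analysis
#'
#' Generates `S_total` studies under the scenario's bivariate binomial model
#' (sizes uniform on the scenario ranges, normal random effects, binomial
#' counts), calibrates the selection intercept on the drawn sizes, and
#' publishes each study independently with probability
#' `Phi(gamma0 + gamma1 * t)` computed from the observed counts (with the
#' zero-cell continuity correction).
#'
#' @param scenario A `srocpb_scenario` from [make_scenario()].
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return A list with `full` and `published` study tibbles (`published` has
#'   zero rows if no study is selected), the logical `published_flags`, the
#'   calibrated `gamma0`, and the per-study selection probabilities.
#' @export
simulate_meta <- function(scenario, seed) {
  stopifnot(inherits(scenario, "srocpb_scenario"))
  set.seed(as.integer(seed))
  S <- scenario$S_total
  pp <- scenario$params
  n1 <- sample(scenario$n1_range[1]:scenario$n1_range[2], S, replace = TRUE)
  n0 <- sample(scenario$n0_range[1]:scenario$n0_range[2], S, replace = TRUE)
  th_s <- rnorm(S, 0, pp[["sigma_theta"]])
  al_s <- rnorm(S, 0, pp[["sigma_alpha"]])
  rates <- study_rates(pp[["theta"]], pp[["alpha"]], pp[["beta"]], th_s, al_s)
  tp <- rbinom(S, n1, rates$tpr)
  fp <- rbinom(S, n0, rates$fpr)
  full <- tibble(label = paste0("study_", seq_len(S)),
                 tp = tp, fp = fp, fn = n1 - tp, tn = n0 - fp)
  class(full) <- c("srocpb_meta", class(full))
  gamma0 <- calibrate_gamma0_sim(n1, n0, pp, scenario$gamma1, scenario$p_target,
                                 scenario$c0, scenario$c1)
  t_obs <- .t_values(tp, fp, n1 - tp, n0 - fp, scenario$c0, scenario$c1)
  p_sel <- pnorm(gamma0 + scenario$gamma1 * t_obs)
  flags <- rbinom(S, 1, p_sel) == 1
  published <- full[flags, , drop = FALSE]
  list(full = full, published = published, published_flags = flags,
       gamma0 = gamma0, select_prob = p_sel)
}

#' Sparsity summary of a meta-analysis
#'
#' Fractions of studies whose minimum 2x2 cell count is zero, at most 3, and
#' at most 5 -- the standard description of how sparse a diagnostic
#' meta-analysis is.
#'
#' @param data A data frame of studies.
#' @return A one-row tibble with `rate_zero`, `rate_le3`, `rate_le5`.
#' @export
sparsity_summary <- function(data) {
  cc <- .meta_counts(data)
  m <- pmin(cc$tp, cc$fp, cc$fn, cc$tn)
  tibble(rate_zero = mean(m == 0), rate_le3 = mean(m <= 3),
         rate_le5 = mean(m <= 5))
}

#' Run a simulation study comparing estimators under selective publication
#'
#' For each replicate, simulates a meta-analysis from the scenario, keeps the
#' published subset, and fits the requested methods: `"naive"` is the
#' unadjusted MLE ignoring selection; `"lnDOR"`, `"sen"`, `"spe"` are
#' selection-adjusted fits at `p = p_target` with weights (1/2, 1/2), (0, 1),
#' (1, 0) respectively (the latter two are deliberately misspecified when the
#' generating mechanism is lnDOR). Replicates whose published subset has
#' fewer than two studies are skipped and counted.
#'
#' @param scenario A `srocpb_scenario`.
#' @param n_reps Number of replicates (>= 2).
#' @param methods Character vector from `c("naive", "lnDOR", "sen", "spe")`.
#' @param seed Master seed; replicate `r` uses seed `seed + r` and is
#'   reproducible in isolation via [simulate_meta()].
#' @param rule Quadrature rule or node count used by the fits.
#' @param keep_estimates If `TRUE`, attach the per-replicate estimates as an
#'   attribute `"estimates"`.
#' @return A tibble with one row per method: mean and SD (across converged
#'   replicates) of the SAUC, theta, alpha, sensitivity and specificity
#'   estimates, plus convergence/skip counts. The scenario's true values are
#'   attached as attribute `"truth"`.
#' @export
run_simulation_study <- function(scenario, n_reps, methods = c("naive", "lnDOR"),
                                 seed = 1, rule = quad_rule(21),
                                 keep_estimates = FALSE) {
  stopifnot(inherits(scenario, "srocpb_scenario"), n_reps >= 2)
  rule <- .as_rule(rule)
  methods <- match.arg(methods, c("naive", "lnDOR", "sen", "spe"),
                       several.ok = TRUE)
  wts <- list(lnDOR = c(1 / 2, 1 / 2), sen = c(0, 1), spe = c(1, 0))
  res <- vector("list", n_reps)
  n_skipped <- 0L
  for (r in seq_len(n_reps)) {
    sim <- simulate_meta(scenario, seed + r)
    pub <- sim$published
    if (nrow(pub) < 2L) {
      n_skipped <- n_skipped + 1L
      next
    }
    naive_fit <- tryCatch(fit_unadjusted(pub, rule = rule), error = function(e) NULL)
    rows <- list()
    for (m in methods) {
      fit <- if (m == "naive") {
        naive_fit
      } else {
        tryCatch(
          fit_sensitivity(pub, p = scenario$p_target,
                          c0 = wts[[m]][1], c1 = wts[[m]][2], rule = rule,
                          start = naive_fit, gamma1_start = 1),
          error = function(e) NULL)
      }
      rows[[m]] <- if (is.null(fit) || !fit$converged) {
        tibble(rep = r, method = m, converged = FALSE, sauc = NA_real_,
               theta = NA_real_, alpha = NA_real_,
               sensitivity = NA_real_, specificity = NA_real_)
      } else {
        tibble(rep = r, method = m, converged = TRUE, sauc = fit$sauc,
               theta = fit$params[["theta"]], alpha = fit$params[["alpha"]],
               sensitivity = unname(fit$sop["sensitivity"]),
               specificity = unname(fit$sop["specificity"]))
      }
    }
    res[[r]] <- dplyr::bind_rows(rows)
  }
  est <- dplyr::bind_rows(res)
  if (nrow(est) == 0L) abort("All replicates were skipped (no published studies).")
  summ <- est |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      n_converged = sum(.data$converged),
      n_failed = sum(!.data$converged),
      dplyr::across(c("sauc", "theta", "alpha", "sensitivity", "specificity"),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop") |>
    dplyr::mutate(n_skipped = n_skipped,
                  method = factor(.data$method, levels = methods)) |>
    dplyr::arrange(.data$method) |>
    dplyr::mutate(method = as.character(.data$method))
  attr(summ, "truth") <- c(sauc = scenario$true_sauc,
                           theta = scenario$params[["theta"]],
                           alpha = scenario$params[["alpha"]],
                           sensitivity = scenario$sens,
                           specificity = scenario$spec)
  if (keep_estimates) attr(summ, "estimates") <- est
  summ
}
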