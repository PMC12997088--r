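#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a fitted SROC model
#'
#' @param x A `srocpb_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error`. Selection parameters (`gamma0`, `gamma1`) are included for
#'   adjusted fits; `gamma1`'s standard error is not reported (the covariance
#'   is computed for the model parameters).
#' @method tidy srocpb_fit
#' @export
tidy.srocpb_fit <- function(x, ...) {
  est <- x$params
  se <- sqrt(pmax(diag(x$vcov), 0))
  out <- tibble(term = names(est), estimate = unname(est), std.error = unname(se))
  if (is.finite(x$gamma1)) {
    out <- dplyr::bind_rows(out, tibble(
      term = c("gamma0", "gamma1"),
      estimate = c(x$gamma0, x$gamma1),
      std.error = NA_real_))
  }
  out
}

#' Glance at a fitted SROC model
#'
#' @param x A `srocpb_fit`.
#' @param ... Unused.
#' @return A one-row tibble: selection probability `p`, SOP coordinates,
#'   SAUC with its standard error and 95% interval, log-likelihood, number of
#'   studies, and convergence flag.
#' @method glance srocpb_fit
#' @export
glance.srocpb_fit <- function(x, ...) {
  tibble(
    p = x$p,
    sensitivity = unname(x$sop["sensitivity"]),
    specificity = unname(x$sop["specificity"]),
    sauc = x$sauc, sauc_se = x$sauc_se,
    sauc_lower = x$sauc_ci[1], sauc_upper = x$sauc_ci[2],
    logLik = x$loglik, n_studies = x$n_studies,
    converged = x$converged
  )
}

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   labs coord_equal theme_minimal geom_ribbon geom_hline facet_wrap
NULL

#' Plot the summary ROC curve of a fit
#'
#' Draws the fitted SROC curve with the summary operating point, and (when
#' the fit carries its data) the observed study points sized by total sample
#' size.
#'
#' @param object A `srocpb_fit`.
#' @param data Optional data frame of studies to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srocpb_fit
#' @export
autoplot.srocpb_fit <- function(object, data = NULL, ...) {
  crv <- sroc_points(object)
  gg <- ggplot(crv, aes(x = .data$fpr, y = .data$sensitivity)) +
    geom_abline(intercept = 0, slope = 1, linetype = "dotted", colour = "grey60") +
    geom_line(colour = "#2c7fb8", linewidth = 0.8)
  if (!is.null(data)) {
    cc <- .meta_counts(data)
    pts <- tibble(fpr = cc$fp / cc$n0, sens = cc$tp / cc$n1,
                  n = cc$n1 + cc$n0)
    gg <- gg + geom_point(data = pts,
                          aes(x = .data$fpr, y = .data$sens, size = .data$n),
                          alpha = 0.5, colour = "grey30") +
      ggplot2::scale_size_area(max_size = 4, guide = "none")
  }
  sopd <- tibble(fpr = 1 - unname(object$sop["specificity"]),
                 sensitivity = unname(object$sop["sensitivity"]))
  gg +
    geom_point(data = sopd, colour = "#d7301f", size = 3, shape = 18) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "False positive rate (1 - specificity)", y = "Sensitivity",
         title = sprintf("SROC curve (SAUC %.3f)", object$sauc)) +
    theme_minimal()
}

#' Plot a sensitivity-analysis curve
#'
#' Shows the estimated SAUC (with its confidence band) as a function of the
#' assumed marginal selection probability `p`, one panel per selection
#' mechanism. Reading from `p = 1` leftwards shows how much of the apparent
#' accuracy could be an artefact of selective publication.
#'
#' @param object A tibble from [sensitivity_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srocpb_curve
#' @export
autoplot.srocpb_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$p, y = .data$sauc)) +
    geom_ribbon(aes(ymin = .data$sauc_lower, ymax = .data$sauc_upper),
                fill = "#2c7fb8", alpha = 0.2) +
    geom_line(colour = "#2c7fb8") +
    geom_point(colour = "#2c7fb8") +
    geom_hline(yintercept = 0.5, linetype = "dotted", colour = "grey60") +
    facet_wrap(~weights) +
    labs(x = "Marginal selection probability p", y = "SAUC") +
    theme_minimal()
}
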