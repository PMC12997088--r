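#' Gauss--Hermite quadrature rule for the random-effects integrals
#'
#' Builds the node/weight set used to integrate over the two independent
#' normal random effects (study-level cut-off and accuracy deviations). The
#' same one-dimensional rule is used in both dimensions; the likelihood code
#' recentres and rescales it per study (adaptive Gauss--Hermite), while the
#' marginal selection probability uses it directly against the prior.
#'
#' @param n_nodes Number of nodes per dimension (integer, at least 5).
#' @return An object of class `srocpb_quad`: a list with `n_nodes`, the 1-D
#'   physicists' Gauss--Hermite `nodes` and `weights`, and the precomputed
#'   tensor-product grid (`z1`, `z2`, `logw` with the `exp(z^2)` factor of the
#'   adaptive rule folded in).
#' @examples
#' r <- quad_rule(21)
#' # integrates a standard normal density to 1
#' sum(r$weights * exp(r$nodes^2) * dnorm(sqrt(2) * r$nodes)) * sqrt(2)
#' @export
quad_rule <- function(n_nodes = 21) {
  n_nodes <- as.integer(n_nodes)
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 5L) {
    abort("`n_nodes` must be a single integer >= 5.")
  }
  gh <- pracma::gaussHermite(n_nodes)
  i <- rep(seq_len(n_nodes), each = n_nodes)
  j <- rep(seq_len(n_nodes), times = n_nodes)
  structure(
    list(
      n_nodes = n_nodes,
      nodes = gh$x,
      weights = gh$w,
      z1 = gh$x[i],
      z2 = gh$x[j],
      # log(w_i w_j) + z_i^2 + z_j^2: weights of the adaptive rule applied to
      # the raw integrand (the Gaussian kernel is part of the integrand here)
      logw = log(gh$w[i]) + log(gh$w[j]) + gh$x[i]^2 + gh$x[j]^2,
      # log(w_i w_j / pi): weights for averaging against the N(0,1)x(0,1) prior
      logw_prior = log(gh$w[i]) + log(gh$w[j]) - log(pi)
    ),
    class = "srocpb_quad"
  )
}

.as_rule <- function(rule) {
  if (inherits(rule, "srocpb_quad")) rule else quad_rule(rule)
}

#' @export
print.srocpb_quad <- function(x, ...) {
  cat("<srocpb_quad> Gauss-Hermite rule,", x$n_nodes, "nodes per dimension\n")
  invisible(x)
}
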