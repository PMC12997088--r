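---
title: "Publication-bias sensitivity analysis for sparse diagnostic meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Publication-bias sensitivity analysis for sparse diagnostic meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(srocpb)
library(dplyr)
```

## The problem

A diagnostic meta-analysis pools 2x2 tables (TP, FP, FN, TN) from studies
that dichotomise a continuous biomarker at heterogeneous cut-offs. Because
cut-offs differ, sensitivity and specificity are negatively correlated across
studies and are summarised jointly by the summary ROC (SROC) curve and the
area under it (SAUC). Two features of real data motivate this package:

* **Sparsity.** When the true sensitivity or specificity is high and groups
  are small, cells of the 2x2 table are frequently zero or near zero. Models
  that normal-approximate the empirical logits need continuity corrections
  and lose calibration. The bivariate *binomial* model keeps the exact
  within-study binomial distributions, so zero cells cost nothing.
* **Selective publication.** Studies with significant accuracy are more
  likely to be published, inflating the pooled SAUC. Since the selection
  process is unobservable, we treat the marginal probability `p` that a
  population study gets published as a *sensitivity parameter* and re-fit
  the model at a sequence of assumed `p` values.

## The model

Study `s` has `n1` diseased and `n0` non-diseased subjects and latent
logistic biomarker distributions. With location `theta + theta_s`, accuracy
`alpha + alpha_s` and log scale-asymmetry `beta`,

* TPR: `pi1 = G{(theta + theta_s + (alpha + alpha_s)/2) e^(-beta/2)}`
* FPR: `pi0 = G{(theta + theta_s - (alpha + alpha_s)/2) e^(+beta/2)}`

with `G` the standard logistic c.d.f. and independent normal random effects
`theta_s ~ N(0, sigma_theta^2)`, `alpha_s ~ N(0, sigma_alpha^2)`.
TP ~ Binomial(n1, pi1) and FP ~ Binomial(n0, pi0) within study. The summary
operating point is the accuracy pair at zero random effects, and eliminating
`theta` gives the SROC curve

    SROC(x) = G{alpha e^(-beta/2) + e^(-beta) logit(x)},     SAUC = int_0^1 SROC(x) dx.

The scaling convention (the diseased-class predictor carries `e^(-beta/2)`)
is the one under which this elimination is exact; it is the standard
hierarchical-SROC parameterisation.

```{r}
ta <- solve_location_scale(0.9, 0.5, beta = 0.15)
ta
sauc(ta[["alpha"]], 0.15)
```

## Selective publication

Publication is modelled as a probit function of the study's t-statistic for
a weighted combination of logit-specificity and logit-sensitivity,
`t = (c0 logit(spe) + c1 logit(sen)) / SE`: a study is published with
probability `Phi(gamma0 + gamma1 t)`. The weights encode the mechanism:
`(1/2, 1/2)` selects on the log diagnostic odds ratio, `(0, 1)` on
sensitivity alone, `(1, 0)` on specificity alone; `t` is invariant to
rescaling the weights. Zero-cell studies get 0.5 added to all four cells
*only* inside this statistic — never in the likelihood.

Conditioning on publication yields the working log-likelihood

    sum_s log f_P(counts_s) + sum_s log Phi(gamma0 + gamma1 t_s)
        - sum_s log P(select | n1_s, n0_s),

and the intercept `gamma0` is not free: given `p`, it solves the empirical
constraint `1/p = mean_s 1/P(select | n1_s, n0_s)`. `P(select | n1, n0)` is
monotone in `gamma0`, so the root is unique; we profile `gamma0` out at every
objective evaluation and maximise over the five model parameters and
`gamma1 >= 0`.

### The marginal selection probability

`P(select | n1, n0)` sums `Phi(gamma0 + gamma1 t(m11, m00))` over all
hypothetical tables against their model probability. Two evaluations are
provided:

* `method = "approx"` (default): given the random effects, the statistic is
  asymptotically normal with mean `mu_U/sigma_U` and unit variance, so the
  inner expectation is `Phi((gamma0 + gamma1 mu_U/sigma_U)/sqrt(1+gamma1^2))`;
  the outer expectation is Gauss–Hermite over the random effects. Cost is
  independent of the group sizes, which is what makes the simulation engine
  affordable.
* `method = "exact"`: the full double sum, with the table probabilities
  marginalised over the random effects by one BLAS product per study and the
  resulting t-distribution binned (400 bins, bin-mean t values) so that the
  intercept profiling stays cheap. Cost grows with `n1 * n0`; at `S = 27`
  CD64-sized studies a fit takes on the order of a minute.

The package carries the exact version both as the reference evaluation for
small meta-analyses and as the oracle that bounds the approximation error.
Across the simulation design grid the typical (median) absolute gap between
the two is below 0.01, but the worst case reaches about 0.08 in the most
heterogeneous scenario at `n1 = 10`, `n0 = 50`, where boundary tables —
whose t-statistic is dominated by the continuity correction — carry
non-negligible probability. We deliberately keep the leading-order form rather than adding
higher-order corrections: the corrections we examined (delta-method `O(1/n)`
mean/variance terms, Edgeworth skewness) degrade accuracy in the
random-effect tails where `n pi (1-pi)` is small, precisely where the error
lives.

## Numerical choices

* **Likelihood integrals:** adaptive Gauss–Hermite, 21 nodes per dimension by
  default. The integrand is log-concave in the random effects, so the
  per-study mode is found by a damped Newton iteration with analytic
  gradient/Hessian (vectorised across studies) and the rule is recentred and
  rescaled there. Doubling the nodes changes the CD64 log-likelihood by less
  than 1e-6. Non-adaptive quadrature is *not* adequate here: with hundreds of
  subjects per study the integrand is far narrower than the random-effect
  prior.
* **SAUC:** Gauss–Legendre after the substitution `x = plogis(u)` (composite,
  256 nodes), exact to near machine precision; confidence intervals by the
  delta method on the logit scale, so they stay inside (0, 1).
* **Optimisation:** `nlminb` on `(theta, alpha, beta, log sigma_theta,
  log sigma_alpha, gamma1)`; sigmas floored at 1e-6; covariance from the
  central finite-difference Hessian of the profiled objective, mapped back to
  the sigma scale by the delta method, with the model-parameter block
  extracted.
* **`gamma1` bounds:** `[0, 8]` by default. The lower bound encodes that
  selection favours significance; at the upper bound the selection function
  is numerically a step function in `t` and the conditional likelihood
  flattens, so fits in small meta-analyses occasionally drift upward without
  gain. Fits pinned at a bound are flagged and their covariance computed at
  fixed `gamma1`; a fit collapsing to `gamma1 = 0` is reported as the
  unadjusted model with `gamma0 = qnorm(p)`.
* **Warm starts:** `sensitivity_curve()` descends from `p = 1`, seeding each
  fit from its neighbour; cold starts at small `p` are unreliable because the
  likelihood surface deforms continuously but is multi-modal.

## Weak identification of the selection slope

With `p` fixed, `gamma1` is estimated from, at best, a couple of dozen
studies, and the profiled conditional log-likelihood is typically *flat over
a wide range of `gamma1`* — on the CD64 data the whole range `gamma1` in
[0, 2.5] spans about two log-likelihood units, with competing local optima
whose SROC summaries differ visibly. Two practical consequences, both
reflected in the package's defaults and worth keeping in mind when comparing
against other implementations of likelihood-based selection models:

1. the location of the maximum is sensitive to how accurately
   `P(select | n1, n0)` is evaluated (differences of a few hundredths per
   study accumulate to several log-likelihood units across terms), which is
   why the exact evaluation is preferred for small meta-analyses; and
2. reported adjusted estimates should be read as "the data are *consistent*
   with accuracy this much lower under this much selection", not as sharp
   point estimates — which is exactly the spirit of a sensitivity analysis.

## The simulation engine

`make_scenario()` encodes six data-generating scenarios: accuracy pairs
(0.9, 0.5), (0.5, 0.9), (0.8, 0.8) with `beta = 0.15` (true SAUC 0.832,
0.798, 0.869), crossed with random-effect SDs (0.6, 1.2) for experiments 1–3
and (1.2, 0.6) for experiments 4–6 (an explicit `sigma_swap` flag runs the
alternative assignment; the sparsity profile of experiment 1 — about 21% of
studies with a zero cell — pins the default one). Group sizes are
`n1 ~ U{10..30}` and `n0 ~ U{200..300}`; selection acts on the lnDOR
t-statistic with slope 1.5, the intercept calibrated on the drawn sizes so
the *average* selection probability equals the target (0.7 by default — note
the design averages `P` itself, while estimation averages `1/P`), and each
study is published by an independent Bernoulli draw.

What the generator emulates: sparse 2x2 tables, realistic group-size
imbalance, cut-off and accuracy heterogeneity, and significance-driven
publication. What it does not: correlated random effects, covariate-driven
selection, non-probit selection, heterogeneous cut-off *reporting*, or
multiple thresholds per study — so passing simulation checks supports
internal consistency of the estimator under its own assumptions, not
robustness to real-world violations of them.

`run_simulation_study()` fits the publication-ignoring MLE and the adjusted
estimator (correctly specified or deliberately misspecified weights) on each
published subset and tabulates means and empirical SDs. Replicate `r` is
seeded as `seed + r`, so any replicate reproduces in isolation. Problem
sizes used in the bundled checks — 200 replicates at 15 studies with a
15-node rule — were chosen so the whole suite runs in tens of minutes on one
CPU; the qualitative bias ordering is already stable at a fraction of that.

```{r, eval = FALSE}
scn <- make_scenario(1, p_target = 0.7, S_total = 15)
run_simulation_study(scn, n_reps = 200, methods = c("naive", "lnDOR"),
                     seed = 1, rule = quad_rule(15))
```

## The CD64 worked example

```{r, eval = FALSE}
cd64 <- read_meta_csv(srocpb_example("cd64.csv"))
fit <- fit_unadjusted(cd64)
glance(fit)
curve <- sensitivity_curve(cd64)   # 3 mechanisms x p = 0.2 ... 1
autoplot(curve)
```

The unadjusted fit reproduces the published summary of this meta-analysis
(SAUC 0.925, SOP (0.819, 0.895)); sweeping `p` downward shows how much
selective publication could account for, mechanism by mechanism.

## Known limitations

* The weights `(c0, c1)` are hyper-parameters of the assumed mechanism, not
  estimated — joint estimation is numerically fragile at realistic `S` and is
  out of scope.
* `p` itself is never estimated; it is the dial of the sensitivity analysis.
* The approximate marginal selection probability is least accurate for very
  small diseased groups (`n1` near 10) in high-heterogeneity scenarios; use
  `method = "exact"` when the meta-analysis is small enough to afford it.
* Confidence intervals for adjusted fits use the observed information of the
  profiled objective and do not propagate uncertainty in `p` or the weights.
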