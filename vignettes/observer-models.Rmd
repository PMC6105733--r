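---
title: "Observer models of interval reproduction under scalar noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models of interval reproduction under scalar noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtiming)
```

## The task and the generative model

`seqtiming` models behaviour in a time-interval reproduction task with two
randomly interleaved trial types. On a *1-2-Go* trial the subject sees a
sample interval `t_s` demarcated once and reproduces it; on a *1-2-3-Go*
trial the same interval is demarcated twice in a row, affording two
measurements before reproduction. Sample intervals are drawn from a
discrete uniform distribution over five values between 600 and 1000 ms.

Timing noise obeys the *scalar property*: its standard deviation grows in
proportion to the timed interval. A measurement is modelled as

    t_m ~ Normal(t_s, (w_m * t_s)^2)

and the production of an interval from an internal estimate `t_e` as

    t_p ~ Normal(t_e + b, (w_p * t_e)^2)

where `w_m` and `w_p` are Weber fractions and `b` a constant offset
absorbing interval-independent response biases. A small fraction `gamma`
of trials are *lapses* on which `t_p` is drawn uniformly between 0 and
2000 ms irrespective of `t_s`.

Scalar noise is the scientific crux. As a function of `t_s` the
measurement likelihood is skewed (longer intervals produce wider
likelihoods), and the product of two such likelihoods is not itself a
member of the family — the package verifies this numerically in its test
suite. Consequently no algorithm that merely updates a fixed set of
posterior parameters (a mean and a variance, say) can integrate two
measurements optimally, which is what makes the comparison of the four
estimators below informative about the underlying inference algorithm.

## The four estimators

All four models are identical on 1-2-Go trials and differ only in how a
second measurement is integrated.

**BLS** (`bls1_map()`, `bls2_map()`) is the Bayes least-squares estimator:
the mean of the posterior obtained by combining the scalar likelihood(s)
with a continuous uniform prior on [600, 1000] ms. Its two-measurement
iso-estimate contours are convex — the larger measurement dominates — a
signature specific to scalar noise (with constant Gaussian noise the
contours are straight lines; `bls2_map(noise = "constant")` exposes this
control).

**BLS_mem** (`blsmem_map()`) allows the first of the two measurements its
own Weber fraction `w_mem`, modelling memory degradation of the first
measurement (or, if `w_mem < w_m`, an attentionally sharpened second
measurement). `w_mem` applies both to the generative noise of the first
measurement and to its weighting in the estimator. With `w_mem = w_m` it
is exactly `bls2_map()`.

**LNE** (`lne_estimate()`) tracks the running average of the measurements
with gains `k_n = 1/n` (1 and 0.5 for the first and second measurement)
and passes the final average through the one-measurement BLS
nonlinearity. Because only the sum of measurements matters, its contours
are straight lines, and because the same nonlinearity is applied
regardless of the number of measurements, it predicts the *same* bias in
both conditions.

**EKF** (`ekf_init()`, `ekf_update()`, `ekf_estimate()`) is a sequential
updater in the spirit of an extended Kalman filter. It starts from the
prior mean with infinite uncertainty (handled symbolically, so the first
gain is exactly 1 and the first estimate is exactly the BLS estimate),
and on each measurement adds a gain-scaled nonlinear function of the
prediction error to the estimate:

    t_e[n] = t_e[n-1] + k_n * fstar(t_m[n] - t_e[n-1])
    fstar(x) = bls1_map(x + t_e0) - t_e0
    k_n = w[n-1]^2 / (w[n-1]^2 + w_m^2)
    w[n] = w[n-1] * w_m / sqrt(w[n-1]^2 + w_m^2)

The reliability recursion follows optimal Gaussian cue combination, so the
second gain is exactly 1/2. The EKF is suboptimal with two measurements
but, unlike LNE, applies its nonlinearity to every innovation and can
therefore reduce bias from the first to the second measurement.

```{r estimators}
pr <- interval_prior()
bls1_map(700, w_m = 0.1, prior = pr)
bls2_map(650, 950, w_m = 0.12, prior = pr)
ekf_estimate(c(650, 950), w_m = 0.1, prior = pr)
lne_estimate(c(650, 950), w_m = 0.1, prior = pr)
```

## Numerical choices

*Quadrature.* All estimator integrals run over the continuous uniform
prior range with composite Simpson's rule on 201 nodes; at this width the
integrands are smooth and the rule is accurate to well below 1e-6
relative error. Trial likelihoods marginalize the unobserved
measurement(s) on Simpson grids centred on `t_s` with half-width 5
measurement SDs (51 nodes per dimension by default). The grids are *not*
truncated at zero — the Gaussian measurement density places no positivity
constraint — and doubling the half-width changes densities by about 1e-5
relative, the Gaussian mass beyond 5 SDs.

*Interpolation.* The one-measurement BLS map is tabulated once per
parameter vector on a 1 ms argument grid wide enough for every innovation
argument the EKF and LNE can request, and interpolated with a monotone
cubic spline; this is what makes the quadrature pipeline fast enough to
sit inside an optimizer. When the cached-density policy is selected
(`quad_config(cache_policy = "grid")`), per-stratum densities are
tabulated on a 1 ms grid and interpolated with a cubic spline, which
agrees with direct evaluation to better than 1e-6 relative error (linear
interpolation would plateau near 3e-5 and was rejected for that reason).
Before the mixture over estimates is evaluated, the two-measurement
estimator cloud (2601 tensor nodes by default) is projected onto a 1 ms
estimate grid by mass- and mean-preserving linear splitting; this leaves
densities unchanged to about 1e-4 relative in the far tails (much less in
the bulk, and dataset log-likelihoods to better than 0.01 nats) while
shrinking the mixture several-fold, which is what makes cross-validated
fitting affordable.

*Degenerate inputs.* Weber fractions are strictly positive; the EKF's
infinite initial uncertainty is treated symbolically (`k_1 = 1`,
`w_1 = w_m`) rather than as floating-point infinity. The estimator maps
are well defined for measurements far outside the prior range and are not
clipped. Two limits deserve note because they differ from naive
expectation: as `w_m` grows the one-measurement estimate converges not to
the prior midpoint but to `(t_max - t_min)/log(t_max/t_min)` (about
783 ms), because the scalar likelihood's `1/t_s` prefactor tilts the
posterior; and the map is strictly increasing only above roughly 380 ms —
below that, shorter measurements carry vanishing information and the map
turns over. Tests assert the true behaviour.

## Fitting

`fit_observer()` maximizes the predictive likelihood of the produced
intervals, marginalized over the latent measurements, under leave-N-out
cross-validation: trials are partitioned into test blocks (100 trials by
default, contiguous in recorded order; a random scheme is available),
the model is fit on each complement, held-out log-likelihood is recorded
per fold, and the final parameters are the mean of the per-fold maxima.
Both conditions share one parameter vector. Fold-wise held-out
log-likelihoods feed `compare_observers()`, which reports mean and
standard error of the log-likelihood ratio of each candidate against the
BLS reference.

The likelihood surface is smooth in the parameters, so the bounded
quasi-Newton search `optim(method = "L-BFGS-B")` with finite-difference
gradients is used rather than a derivative-free method; restarts are
drawn by Latin hypercube from a plausible box (`w_m, w_p` in roughly the
human range 0.03–0.3, small `b` and `gamma`). Box bounds are
`w_m, w_p ∈ [1e-3, 0.5]`, `b ∈ [-300, 300]` ms, `gamma ∈ [0, 0.3]`,
`w_mem ∈ [1e-3, 1]`.

Lapse trials are identified after fitting as those where the lapse branch
of the mixture outweighs the non-lapse branch,
`gamma * p(t_p | lapse) > (1 - gamma) * p(t_p | t_s, Theta)`, with the
non-lapse density marginalized over the latent measurements (the internal
estimate is not observable, so the comparison is made at the level of
observables).

## Summary statistics

`bias_var_rmse()` computes, over the distinct sample intervals,
`BIAS^2` (mean squared deviation of per-`t_s` mean production from
`t_s`), `VAR` (mean within-`t_s` variance) and
`RMSE = sqrt(BIAS^2 + VAR)`, on non-lapse trials after removing the
fitted offset. Within-`t_s` variance uses the unbiased `n - 1`
denominator; the convention is held fixed across observed and
model-expected statistics and in every oracle in the test suite.
`expected_model_stats()` obtains the model-expected statistics by
averaging over repeated simulation (1000 datasets by default) with trial
counts matched per sample interval, without lapses and with zero offset.
`rmse_permutation_test()` compares the RMSE of the two conditions by
shuffling condition labels within each `t_s` stratum, which preserves
each condition's sample-interval composition under the null; the
stratified construction is the conservative choice for a statistic that
is defined per `t_s`.

## The synthetic-data generator

`simulate_session()` emulates the full experiment: `t_s` i.i.d. from the
5-point support, conditions randomly interleaved (half 1-2-3-Go by
default), lapses at rate `gamma` uniform on [0, 2000] ms, measurement and
production noise exactly as in the generative model above, and the
adaptive feedback staircase — a relative-error threshold initialized at
0.15 and moved by 0.001 down after a correct and up after an incorrect
response (one-up/one-down), which equilibrates near 50% correct. The
comparison against the threshold is inclusive (`<=`); the boundary
convention is not behaviourally identifiable and is simply documented.
Negative productions, possible in principle under Gaussian production
noise, are redrawn rather than truncated; at realistic parameters the
redraw frequency is negligible, so the positive-side Gaussian shape is
essentially intact. The staircase only scores trials — no feedback term
enters the generative process, since none of the models contains one.
`apply_exclusions()` implements the standard trial filters: the first 99
trials of each session (adaptation to the prior), anticipations
(`t_p <= 0`, which the generator itself never produces but imported data
may contain), and responses later than 1000 ms after the veridical
interval, with the boundary kept.

What the generator does *not* emulate: sequential dependencies between
trials (drifts in attention, autocorrelated noise), correlations between
the two measurements of a 1-2-3-Go trial (the middle flash is shared, a
caveat the models inherit), non-uniform subjective priors, and
non-quadratic cost functions. Passing tests on synthetic data therefore
demonstrate the internal consistency of the pipeline — the fitting
machinery recovers the parameters and identity of the model that
generated the data — not that these models are the right description of
any particular dataset.

```{r session}
th <- observer_params("bls", w_m = 0.1, w_p = 0.08, gamma = 0.02)
s <- simulate_session(2000, th, seed = 1)
bias_var_rmse(s)
```

## Validation strategy and problem sizes

Every quadrature-based quantity is checked against an independent oracle:
estimator maps against self-normalized importance-sampling posterior
means (1e6 draws, 3 Monte-Carlo SEs), marginal densities against
histograms of forward-simulated productions (binomial SEs per bin), and
the summary statistics against hand-computed tables. Exact identities —
one-measurement EKF and LNE equal to the BLS map, the memory variant at
`w_mem = w_m` equal to the two-measurement map, the recursive posterior
equal to the batch posterior — are asserted to 1e-9.

Recovery experiments use sizes chosen to exercise the full machinery at
desk scale: parameter recovery fits 2000 simulated trials; model recovery
simulates 4000 trials from each of the four models at
`(w_m, w_p, gamma, b) = (0.1, 0.08, 0.02, 10 ms)` and fits all four with
two 2000-trial cross-validation folds and a single optimizer start, which
is sufficient for the generating model to attain the highest held-out
log-likelihood; the bias-pattern checks use 4000 EKF-generated trials
with 200-replicate model-expected statistics. The bias-pattern checks
simulate a low-sensitivity observer (`w_m = 0.2, w_p = 0.1`): the excess
two-measurement bias that distinguishes the EKF from the optimal
estimator grows with measurement noise and only emerges above
`w_m` of roughly 0.15 — at lower noise the EKF's suboptimality appears
as excess variance rather than excess bias. These sizes are the
package's own choices and are stated here so they can be scaled up when
more precision is wanted.

## Known limitations

The trial likelihood assumes the two measurements are conditionally
independent given `t_s`; the estimator family assumes the quadratic-loss
posterior mean and an accurate internal copy of the uniform prior.
Fitting assumes both conditions share one parameter vector. The
comparison machinery reports held-out log-likelihood ratios, not posterior
model probabilities; with few folds the standard errors are coarse. None
of the models describes reaction-time components of the response or
sequential effects across trials.
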