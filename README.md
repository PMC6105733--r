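# seqtiming

Observer models of human time-interval reproduction under scalar
(signal-dependent) noise, for researchers studying Bayesian integration
and its algorithmic approximations in timing behaviour.

In the modelled task a sample interval `t_s` (discrete uniform,
600–1000 ms, 5 values) is demarcated once (*1-2-Go*) or twice
(*1-2-3-Go*) and then reproduced, yielding a production interval `t_p`.
Timing noise obeys the scalar property — measurement noise is
`Normal(t_s, (w_m t_s)^2)` and production noise
`Normal(t_e + b, (w_p t_e)^2)` — with a lapse mixture (rate `gamma`,
uniform on 0–2000 ms). Because the scalar likelihood family is not closed
under multiplication, integrating *two* measurements optimally requires
updating a full posterior, and comparing estimators on such data reveals
which inference algorithm the data support. The package implements four:

* **BLS** — Bayes least-squares (posterior mean) with one or two
  measurements: `f_BLS1(t_m1) = E[t_s | t_m1]`,
  `f_BLS2(t_m1, t_m2) = E[t_s | t_m1, t_m2]` under a uniform prior on
  [600, 1000] ms;
* **BLS_mem** — BLS with a separate Weber fraction `w_mem` for the first
  of two measurements (memory degradation);
* **LNE** — linear-nonlinear estimator: running average with gains
  `k_n = 1/n`, passed through `f_BLS1`;
* **EKF** — extended-Kalman-filter-style updater
  `t_e[n] = t_e[n-1] + k_n f*(t_m[n] - t_e[n-1])` with
  `f*(x) = f_BLS1(x + t_e0) - t_e0`,
  `k_n = w[n-1]^2/(w[n-1]^2 + w_m^2)` and cue-combination propagation of
  the estimate's Weber fraction.

Around them: Simpson-quadrature trial likelihoods
`p(t_p | t_s, Θ)` marginalized over the latent measurements,
leave-N-out cross-validated maximum-likelihood fitting
(`fit_observer()`), held-out model comparison (`compare_observers()`),
lapse-trial identification, `BIAS²/VAR/RMSE` decompositions with
stratified permutation tests, and a full task simulator including the
one-up/one-down correctness staircase (`simulate_session()`).

## Worked example

Simulate an EKF observer, apply the standard exclusions, fit EKF and BLS
by cross-validated maximum likelihood, and compare:

```r
library(seqtiming)
th <- observer_params("ekf", w_m = 0.1, w_p = 0.08, b = 10, gamma = 0.02)
sess <- simulate_session(1200, th, seed = 42, with_staircase = TRUE)
trials <- apply_exclusions(sess, warmup = 99)

fit <- fit_observer(trials, "ekf",
                    control = fit_control(test_block_size = 500,
                                          restarts = 1, seed = 1))
fit
#> Observer model fit [EKF]
#>   1099 trials, 2 fold(s) (contiguous blocks of 500)
#>   averaged ML parameters:
#>     w_m = 0.09839, w_p = 0.08054, b = 10.91, gamma = 0.01267
#>   mean held-out log-likelihood per fold: -3216.04 nats

fit_bls <- fit_observer(trials, "bls",
                        control = fit_control(test_block_size = 500,
                                              restarts = 1, seed = 1))
compare_observers(fit, reference = fit_bls)
#> Held-out log-likelihood ratios vs BLS (per fold mean, SE)
#>  model mean_llr se_llr n_folds
#>    EKF   0.9879 0.2144       2
```

The fit recovers the generating Weber fractions (0.098 and 0.081 against
true values 0.10 and 0.08), and the positive held-out log-likelihood
ratio correctly prefers the generating EKF model over BLS. Summary
statistics after offset removal and lapse exclusion show the expected
improvement from the second measurement:

```r
lapse <- classify_lapse_trials(trials, fit$params)
bias_var_rmse(trials, offset = fit$params$b, lapse = lapse)
#>   condition  bias_sq      var     rmse n_distinct_ts   source
#> 1       12G 2785.225 6673.133 97.25409             5 observed
#> 2      123G 1079.163 6014.136 84.22173             5 observed
```

RMSE drops from 97.3 ms to 84.2 ms between the one- and two-measurement
conditions, driven by reductions in both squared bias and variance.

The methods vignette (`vignettes/observer-models.Rmd`) documents the
model equations, quadrature and interpolation choices, fitting and
validation strategy, and the generator's scope.

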