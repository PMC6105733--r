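# Shared fixtures and independent Monte-Carlo oracles. The oracles never
# call the quadrature code paths they are used to check.

default_prior <- interval_prior()

# Self-normalized importance-sampling estimate of the posterior mean
# E[t_s | measurements] under the uniform prior and scalar likelihood(s),
# with its Monte-Carlo standard error. Directly evaluates the Gaussian
# density; no quadrature, no estimator code.
mc_posterior_mean <- function(tm1, tm2 = NULL, w1, w2 = w1,
                              prior = default_prior, n = 1e6) {
  ts <- runif(n, prior$t_min, prior$t_max)
  lw <- dnorm(tm1, ts, w1 * ts)
  if (!is.null(tm2)) lw <- lw * dnorm(tm2, ts, w2 * ts)
  est <- sum(lw * ts) / sum(lw)
  se <- sqrt(sum(lw^2 * (ts - est)^2)) / sum(lw)
  list(est = est, se = se)
}

# Forward-simulate the generative process of one stratum (no quadrature):
# returns produced intervals for Monte-Carlo checks of the marginal
# densities. The estimator itself is evaluated through the package maps,
# which are independently validated against mc_posterior_mean.
mc_simulate_tp <- function(n, t_s, condition, params, prior = default_prior) {
  w1 <- if (params$model == "bls_mem" && condition == "123G")
    params$w_mem else params$w_m
  tm1 <- rnorm(n, t_s, w1 * t_s)
  if (condition == "12G") {
    te <- bls1_map(tm1, params$w_m, prior)
  } else {
    tm2 <- rnorm(n, t_s, params$w_m * t_s)
    te <- switch(params$model,
      bls = bls2_map(tm1, tm2, params$w_m, prior),
      bls_mem = blsmem_map(tm1, tm2, params$w_mem, params$w_m, prior),
      lne = bls1_map((tm1 + tm2) / 2, params$w_m, prior),
      ekf = {
        te1 <- bls1_map(tm1, params$w_m, prior)
        te1 + 0.5 * (bls1_map(tm2 - te1 + prior$mean, params$w_m, prior) -
                       prior$mean)
      })
  }
  tp <- rnorm(n, te + params$b, params$w_p * te)
  if (params$gamma > 0) {
    lapse <- runif(n) < params$gamma
    tp[lapse] <- runif(sum(lapse), params$lapse_range[1L],
                       params$lapse_range[2L])
  }
  tp
}

# Compare a density to the histogram of Monte-Carlo draws: all bins within
# 'z_max' binomial standard errors. Returns the largest |z|.
mc_density_zmax <- function(draws, dens_fun, lo, hi, bin = 20) {
  br <- seq(lo, hi, by = bin)
  h <- hist(draws[draws >= lo & draws <= hi], breaks = br, plot = FALSE)
  p_hat <- h$counts / length(draws)
  p_thr <- dens_fun(h$mids) * bin
  se <- sqrt(p_thr * (1 - p_thr) / length(draws))
  max(abs(p_hat - p_thr) / se)
}

# single-condition session (uses the package generator)
sim_cond <- function(params, n, condition = "12G", prior = default_prior) {
  simulate_session(n, params, prior = prior,
                   condition_mix = if (condition == "123G") 1 else 0)
}

# Simpson integral of a tabulated function on a uniform grid (odd length)
simpson_int <- function(x, y) sum(simpson_weights(length(x), x[2] - x[1]) * y)
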