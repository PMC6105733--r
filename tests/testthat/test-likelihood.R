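pr <- default_prior
th <- observer_params("bls", w_m = 0.1, w_p = 0.08, b = 20, gamma = 0.02)

test_that("marginal predictive densities are proper and respect the lapse
           floor", {
  tp <- seq(0, 2000, length.out = 2001)
  sw <- simpson_weights(2001, 1)
  for (cond in c("12G", "123G")) {
    dens <- p_tp_given_ts(tp, 800, cond, th, pr)
    expect_true(all(dens >= 0))
    expect_equal(sum(sw * dens), 1, tolerance = 1e-3)
    expect_true(all(dens >= th$gamma / 2000 - 1e-12))
  }
  # pure lapse: flat over the lapse window regardless of t_s
  th1 <- observer_params("bls", w_m = 0.1, w_p = 0.08, gamma = 1)
  expect_equal(p_tp_given_ts(c(10, 700, 1900), 600, "12G", th1, pr),
               rep(1 / 2000, 3))
  expect_error(quad_config(n_nodes_tm = 50), "odd")
  expect_error(quad_config(span_sigmas = 2), "span")
})

test_that("two-measurement BLS integrand is symmetric in the measurement
           grid dimensions", {
  # swapping which grid dimension carries t_m1 vs t_m2 transposes the
  # estimate tensor; for BLS the tensor must be transpose-symmetric
  a <- seq(500, 1100, length.out = 31)
  te_ab <- seqtiming:::bls2_tensor(a, a, 0.1, 0.1, pr)
  expect_lt(max(abs(te_ab - t(te_ab))), 1e-9)
  # and for distinct grids the swap is an exact transpose
  b <- seq(550, 1150, length.out = 31)
  expect_lt(max(abs(seqtiming:::bls2_tensor(a, b, 0.1, 0.1, pr) -
                      t(seqtiming:::bls2_tensor(b, a, 0.1, 0.1, pr)))),
            1e-9)
  # asymmetric measurement noise breaks the symmetry (memory variant)
  te_mem <- seqtiming:::bls2_tensor(a, a, 0.25, 0.1, pr)
  expect_gt(max(abs(te_mem - t(te_mem))), 1)
})

test_that("marginal density matches Monte-Carlo simulation of the
           generative process", {
  the <- observer_params("ekf", w_m = 0.1, w_p = 0.1, b = 0, gamma = 0)
  set.seed(21)
  draws <- mc_simulate_tp(4e5, 800, "123G", the)
  z <- mc_density_zmax(draws, function(x)
    p_tp_given_ts(x, 800, "123G", the, pr), 450, 1150, bin = 20)
  expect_lt(z, 3.5)
  # one-measurement case, concentrated production noise: mean of the
  # density matches the Monte-Carlo mean of simulated productions
  thc <- observer_params("bls", w_m = 0.1, w_p = 0.01, b = 0, gamma = 0)
  set.seed(22)
  d1 <- mc_simulate_tp(2e5, 700, "12G", thc)
  tp <- seq(400, 1300, by = 0.5)
  dens <- p_tp_given_ts(tp, 700, "12G", thc, pr)
  mu_dens <- sum(tp * dens) / sum(dens)
  expect_lt(abs(mu_dens - mean(d1)), 3 * sd(d1) / sqrt(length(d1)))
})

test_that("cached density tables agree with direct evaluation", {
  set.seed(31)
  d <- simulate_session(1000, th, seed = 31)
  ll_direct <- dataset_loglik(d, th, pr, quad_config())
  ll_grid <- dataset_loglik(d, th, pr, quad_config(cache_policy = "grid"))
  expect_equal(ll_grid, ll_direct, tolerance = 1e-7)
  # pointwise relative agreement at random probes
  probes <- runif(1000, 100, 1900)
  direct <- p_tp_given_ts(probes, 800, "123G", th, pr)
  tab_grid <- seq(0, 2000, by = 1)
  tab <- p_tp_given_ts(tab_grid, 800, "123G", th, pr)
  sf <- splinefun(tab_grid, tab, method = "natural")
  expect_lt(max(abs(sf(probes) - direct) / direct), 1e-6)
})

test_that("the 5-SD measurement-grid truncation is adequate", {
  tp <- seq(300, 1500, by = 10)
  d5 <- p_tp_given_ts(tp, 800, "123G", th, pr, quad_config(101))
  d10 <- p_tp_given_ts(tp, 800, "123G", th, pr,
                       quad_config(101, span_sigmas = 10))
  expect_lt(max(abs(d5 - d10) / d10), 5e-5)
})

test_that("dataset log-likelihood is additive, matches the single-trial
           density, and runs within the runtime contract", {
  one <- data.frame(condition = "123G", ts_ms = 800, tp_ms = 750)
  expect_equal(dataset_loglik(one, th, pr),
               log(p_tp_given_ts(750, 800, "123G", th, pr)))
  d <- simulate_session(400, th, seed = 41)
  h1 <- d[1:200, ]
  h2 <- d[201:400, ]
  expect_equal(dataset_loglik(d, th, pr),
               dataset_loglik(h1, th, pr) + dataset_loglik(h2, th, pr))
  # zero-density trial with gamma = 0 warns and returns -Inf
  th0 <- observer_params("bls", w_m = 0.05, w_p = 0.05, gamma = 0)
  bad <- data.frame(condition = "12G", ts_ms = 800, tp_ms = 1999)
  expect_warning(ll <- dataset_loglik(bad, th0, pr), "zero")
  expect_identical(ll, -Inf)
  # runtime contract: one 800-trial evaluation well under 5 s
  d800 <- simulate_session(800, th, seed = 42)
  elapsed <- system.time(dataset_loglik(d800, th, pr))[["elapsed"]]
  expect_lt(elapsed, 5)
})

test_that("the generating parameters beat a mis-scaled alternative on
           simulated data", {
  th_true <- observer_params("bls", w_m = 0.1, w_p = 0.08, gamma = 0.02)
  th_bad <- observer_params("bls", w_m = 0.2, w_p = 0.08, gamma = 0.02)
  set.seed(51)
  wins <- vapply(1:20, function(i) {
    d <- simulate_session(500, th_true)
    dataset_loglik(d, th_true, pr) > dataset_loglik(d, th_bad, pr)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
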