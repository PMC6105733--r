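pr <- default_prior

test_that("scalar likelihood is the signal-scaled Gaussian density", {
  # peak value at the mean, and the closed form at an off-peak point
  expect_equal(scalar_likelihood(800, 800, 0.1), 1 / (sqrt(2 * pi) * 80))
  expect_equal(scalar_likelihood(700, 800, 0.1), dnorm(700, 800, 80))
  tm <- seq(800 - 8 * 80, 800 + 8 * 80, length.out = 1601)
  expect_equal(simpson_int(tm, scalar_likelihood(tm, 800, 0.1)), 1,
               tolerance = 1e-9)
  expect_error(scalar_likelihood(700, -800, 0.1), "t_s")
  expect_error(scalar_likelihood(700, 800, 0), "w")
})

test_that("posterior is normalized, supported on the prior range, and the
           recursive form equals the batch form", {
  g <- seq(550, 1050, by = 1)
  p1 <- posterior_interval(g, 750, w_m = 0.15, prior = pr)
  expect_true(all(p1 >= 0))
  expect_true(all(p1[g < 600 | g > 1000] == 0))
  ins <- g >= 600 & g <= 1000
  expect_equal(sum((p1[ins][-1] + p1[ins][-sum(ins)]) / 2), 1,
               tolerance = 1e-6)
  # recursive vs batch on 100 random triples
  set.seed(42)
  gg <- seq(600, 1000, by = 2)
  for (i in 1:100) {
    m1 <- runif(1, 500, 1100)
    m2 <- runif(1, 500, 1100)
    w <- runif(1, 0.03, 0.4)
    pb <- posterior_interval(gg, m1, m2, w, pr, method = "batch")
    prc <- posterior_interval(gg, m1, m2, w, pr, method = "recursive")
    expect_lt(max(abs(pb - prc)), 1e-9)
  }
  # two identical measurements sharpen the posterior
  sd_of <- function(p) {
    mu <- sum(gg * p) / sum(p)
    sqrt(sum((gg - mu)^2 * p) / sum(p))
  }
  p_one <- posterior_interval(gg, 750, w_m = 0.15, prior = pr)
  p_two <- posterior_interval(gg, 750, 750, w_m = 0.15, prior = pr)
  expect_lt(sd_of(p_two), sd_of(p_one))
  expect_error(posterior_interval(seq(700, 900, 1), 750, w_m = 0.1,
                                  prior = pr), "cover")
  # posterior matches a rejection-sampling histogram of t_s | t_m1
  set.seed(7)
  n <- 4e5
  ts_prop <- runif(n, 600, 1000)
  tm_draw <- rnorm(n, ts_prop, 0.15 * ts_prop)
  keep <- abs(tm_draw - 750) < 4   # accept draws with t_m near 750
  br <- seq(600, 1000, by = 25)
  h <- hist(ts_prop[keep], breaks = br, plot = FALSE, right = FALSE)
  gg2 <- seq(600.25, 999.75, by = 0.5)
  pq <- posterior_interval(c(600, gg2, 1000), 750, w_m = 0.15, prior = pr)
  pq <- pq[-c(1L, length(pq))]
  bin <- cut(gg2, br, right = FALSE)
  p_thr <- as.numeric(tapply(pq, bin, sum))
  p_thr <- p_thr / sum(p_thr)
  p_hat <- h$counts / sum(keep)
  se <- sqrt(p_thr * (1 - p_thr) / sum(keep))
  expect_true(all(abs(p_hat - p_thr) < 4 * se))
})

test_that("one-measurement BLS map: limits, monotonicity, regression to
           the mean, and agreement with the importance-sampling oracle", {
  # noiseless limit inside the prior range
  expect_equal(bls1_map(c(650, 700, 900), 1e-4, pr), c(650, 700, 900),
               tolerance = 1e-6)
  # flat-likelihood limit: the 1/t_s prefactor tilts the posterior, so the
  # limit is (t_max - t_min)/log(t_max/t_min), not the prior midpoint
  expect_equal(bls1_map(c(600, 800, 1000), 1e6, pr),
               rep(400 / log(1000 / 600), 3), tolerance = 1e-3)
  # bounded and monotone on the behaviourally relevant argument range
  v <- bls1_map(seq(400, 2000, by = 1), 0.1, pr)
  expect_true(all(v > 600 & v < 1000))
  expect_true(all(diff(v) > 0))
  # regression toward the mean
  expect_gt(bls1_map(600, 0.15, pr), 600)
  expect_lt(bls1_map(1000, 0.15, pr), 1000)
  # oracle agreement
  set.seed(101)
  mc <- mc_posterior_mean(700, w1 = 0.1)
  expect_lt(abs(bls1_map(700, 0.1, pr) - mc$est), 3 * mc$se)
})

test_that("two-measurement BLS map is symmetric, convex-contoured, and
           matches independent oracles", {
  a <- runif(20, 550, 1100)
  b <- runif(20, 550, 1100)
  expect_equal(bls2_map(a, b, 0.12, pr), bls2_map(b, a, 0.12, pr))
  expect_equal(bls2_map(800, 800, 1e-4, pr), 800, tolerance = 1e-6)
  # Monte-Carlo oracle at a probe pair
  set.seed(102)
  mc <- mc_posterior_mean(650, 950, w1 = 0.12)
  expect_lt(abs(bls2_map(650, 950, 0.12, pr) - mc$est), 3 * mc$se)
  # high-resolution independent quadrature (midpoint rule, 1e5 nodes)
  ts <- seq(600.002, 999.998, length.out = 1e5)
  lk <- dnorm(650, ts, 0.12 * ts) * dnorm(950, ts, 0.12 * ts)
  expect_equal(bls2_map(650, 950, 0.12, pr), sum(ts * lk) / sum(lk),
               tolerance = 1e-6)
  # convex iso-contours: along t_m1 + t_m2 = const the estimate grows with
  # the asymmetry (the larger measurement dominates)
  d <- seq(0, 300, by = 50)
  est <- bls2_map(800 + d, 800 - d, 0.12, pr)
  expect_true(all(diff(est) > 0))
})

test_that("memory-augmented BLS reduces to BLS2 at w_mem = w_m and loses
           first-measurement influence as w_mem grows", {
  a <- seq(600, 1000, by = 50)
  expect_lt(max(abs(blsmem_map(a, rev(a), 0.1, 0.1, pr) -
                      bls2_map(a, rev(a), 0.1, pr))), 1e-9)
  # w_mem >> w_m: the estimate no longer depends on t_m1
  hi <- blsmem_map(c(600, 800, 1000), 900, 1e5, 0.1, pr)
  expect_lt(max(hi) - min(hi), 1e-3)
  # w_mem > w_m weighs t_m2 more: moving t_m2 moves the estimate more
  # than moving t_m1 by the same amount
  d_tm2 <- blsmem_map(750, 900, 0.2, 0.1, pr) -
    blsmem_map(750, 850, 0.2, 0.1, pr)
  d_tm1 <- blsmem_map(800, 850, 0.2, 0.1, pr) -
    blsmem_map(750, 850, 0.2, 0.1, pr)
  expect_gt(d_tm2, d_tm1)
  # independent quadrature oracle
  ts <- seq(600.002, 999.998, length.out = 1e5)
  lk <- dnorm(600, ts, 0.2 * ts) * dnorm(1000, ts, 0.1 * ts)
  expect_equal(blsmem_map(600, 1000, 0.2, 0.1, pr),
               sum(ts * lk) / sum(lk), tolerance = 1e-6)
})

test_that("EKF update: first estimate equals BLS, gains and reliabilities
           follow the cue-combination recursion, order matters", {
  s <- ekf_init(pr)
  expect_identical(s$n, 0L)
  expect_equal(s$t_e, 800)
  expect_true(is.infinite(s$w))
  s1 <- ekf_update(s, 700, 0.1, pr)
  expect_equal(s1$last_gain, 1)
  expect_equal(s1$w, 0.1)
  expect_equal(s1$t_e, bls1_map(700, 0.1, pr))
  s2 <- ekf_update(s1, 900, 0.1, pr)
  expect_equal(s2$last_gain, 0.5)
  expect_equal(s2$w, 0.1 / sqrt(2))
  expect_lt(s2$w, s1$w)  # reliability strictly improves with data
  # hand trace of two updates through the one-measurement map
  te1 <- bls1_map(700, 0.1, pr)
  expect_equal(s2$t_e, te1 + 0.5 * (bls1_map(900 - te1 + 800, 0.1, pr) - 800))
  # chained interface
  expect_equal(ekf_estimate(c(700, 900), 0.1, pr), s2$t_e)
  expect_equal(ekf_estimate(700, 0.1, pr), bls1_map(700, 0.1, pr))
  # not symmetric in measurement order, but always bounded
  e_ab <- ekf_estimate(c(650, 950), 0.1, pr)
  e_ba <- ekf_estimate(c(950, 650), 0.1, pr)
  expect_gt(abs(e_ab - e_ba), 1)
  expect_true(all(c(e_ab, e_ba) > 600 & c(e_ab, e_ba) < 1000))
  expect_error(ekf_estimate(numeric(0), 0.1, pr), "measurement")
  expect_error(ekf_update(s, 700, -1, pr), "w_m")
})

test_that("LNE tracks the running average with gains 1/n and passes it
           through the one-measurement BLS nonlinearity", {
  d <- lne_estimate(c(700, 900), 0.1, pr, details = TRUE)
  expect_equal(d$gains, c(1, 0.5))
  expect_equal(d$running_mean, c(700, 0.5 * (700 + 900)))
  expect_equal(d$estimate, bls1_map(800, 0.1, pr))
  expect_equal(lne_estimate(700, 0.1, pr), bls1_map(700, 0.1, pr))
  # order invariance
  set.seed(3)
  for (i in 1:10) {
    m <- runif(2, 550, 1100)
    expect_equal(lne_estimate(m, 0.1, pr), lne_estimate(rev(m), 0.1, pr))
  }
  expect_error(lne_estimate(numeric(0), 0.1, pr), "measurement")
})

test_that("production and lapse-mixture densities have the stated shape", {
  expect_equal(production_density(880, 800, 0.1, b = 80),
               1 / (sqrt(2 * pi) * 80))
  tp <- seq(800 - 640, 800 + 640, length.out = 1281)
  expect_equal(simpson_int(tp, production_density(tp, 800, 0.1)), 1,
               tolerance = 1e-6)
  th0 <- observer_params("bls", w_m = 0.1, w_p = 0.1, gamma = 0)
  expect_equal(response_mixture_density(tp, 800, th0),
               production_density(tp, 800, 0.1))
  th1 <- observer_params("bls", w_m = 0.1, w_p = 0.1, gamma = 1)
  expect_equal(response_mixture_density(c(0, 500, 2000), 800, th1),
               rep(1 / 2000, 3))
  expect_equal(response_mixture_density(2500, 800, th1), 0)
  th05 <- observer_params("bls", w_m = 0.1, w_p = 0.05, gamma = 0.05)
  expect_equal(response_mixture_density(1990, 800, th05), 0.05 / 2000,
               tolerance = 1e-6)
  expect_error(production_density(800, -10, 0.1), "t_e")
})
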