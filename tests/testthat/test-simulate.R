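pr <- default_prior
th <- observer_params("bls", w_m = 0.1, w_p = 0.08, b = 20, gamma = 0.02)

test_that("sessions are seed-reproducible and sample the task design", {
  s1 <- simulate_session(5000, th, seed = 7)
  s2 <- simulate_session(5000, th, seed = 7)
  expect_identical(s1, s2)
  # t_s uniform over the 5-value support
  freq <- table(factor(s1$ts_ms, levels = pr$support)) / nrow(s1)
  expect_true(all(abs(freq - 0.2) < 3 * sqrt(0.2 * 0.8 / 5000)))
  # condition mix
  expect_lt(abs(mean(s1$condition == "123G") - 0.5),
            3 * sqrt(0.25 / 5000))
  # latents recorded except on lapse trials
  expect_true(all(is.na(s1$tm1_ms[s1$is_lapse])))
  expect_true(all(!is.na(s1$te_ms[!s1$is_lapse])))
  expect_true(all(is.na(s1$tm2_ms[s1$condition == "12G" & !s1$is_lapse])))
  expect_true(all(s1$tp_ms >= 0))
  expect_error(simulate_session(0, th), "n_trials")
})

test_that("lapse trials occur at rate gamma and are uniform", {
  thl <- observer_params("bls", w_m = 0.1, w_p = 0.08, gamma = 0.1)
  s <- simulate_session(20000, thl, seed = 8)
  expect_lt(abs(mean(s$is_lapse) - 0.1), 3 * sqrt(0.1 * 0.9 / 20000))
  ks <- suppressWarnings(
    stats::ks.test(s$tp_ms[s$is_lapse], "punif", 0, 2000))
  expect_gt(ks$p.value, 0.01)
})

test_that("noiseless observers reproduce the sample interval", {
  th0 <- observer_params("bls", w_m = 1e-4, w_p = 1e-4, b = 0, gamma = 0)
  s <- simulate_session(50, th0, seed = 9)
  expect_lt(max(abs(s$tp_ms - s$ts_ms)), 1)
})

test_that("simulated production moments match the predictive density", {
  thc <- observer_params("ekf", w_m = 0.1, w_p = 0.08, b = 20, gamma = 0)
  s <- simulate_session(40000, thc, seed = 10)
  tp <- seq(0, 2000, by = 1)
  for (cond in c("12G", "123G")) {
    sel <- s$condition == cond & s$ts_ms == 800
    dens <- p_tp_given_ts(tp, 800, cond, thc, pr)
    mu <- sum(tp * dens) / sum(dens)
    n <- sum(sel)
    expect_lt(abs(mean(s$tp_ms[sel]) - mu),
              3 * sd(s$tp_ms[sel]) / sqrt(n))
    sd_thr <- sqrt(sum((tp - mu)^2 * dens) / sum(dens))
    expect_lt(abs(sd(s$tp_ms[sel]) - sd_thr), 3 * sd_thr / sqrt(2 * n))
  }
})

test_that("one-up/one-down staircase bookkeeping follows the rule", {
  st <- staircase_state()
  expect_equal(st$k, 0.15)
  expect_equal(staircase_update(st, TRUE)$k, 0.149)
  expect_equal(staircase_update(st, FALSE)$k, 0.151)
  # alternation returns to the start after each pair
  s2 <- staircase_update(staircase_update(st, TRUE), FALSE)
  expect_equal(s2$k, st$k)
  # floored at the step size
  low <- staircase_state(k = 0.001, step = 0.001)
  expect_equal(staircase_update(low, TRUE)$k, 0.001)
  # session-level scoring matches the scalar rule
  s <- simulate_session(300, th, seed = 11, with_staircase = TRUE)
  expect_true(all(s$correct ==
                    (abs(s$tp_ms - s$ts_ms) / s$ts_ms <= s$threshold_at_trial)))
  step_dir <- diff(s$threshold_at_trial)
  expect_true(all(step_dir[s$correct[-nrow(s)]] <= 0))
  st_final <- attr(s, "staircase")
  expect_s3_class(st_final, "staircase_state")
  expect_equal(nrow(st_final$history), 300)
})

test_that("exclusion rules: warm-up trials, anticipations, and the
           inclusive response window", {
  d <- data.frame(session = 1, index = 1:100,
                  condition = "12G", ts_ms = 800, tp_ms = 800)
  out <- apply_exclusions(d)
  expect_equal(nrow(out), 1L)   # 100 trials, 99 warm-up
  expect_equal(unname(attr(out, "excluded")["warmup"]), 99)
  d2 <- data.frame(session = 1, index = 1:4, condition = "12G",
                   ts_ms = c(600, 1000, 800, 800),
                   tp_ms = c(1700, 1999, -5, 1800))
  out2 <- apply_exclusions(d2, warmup = 0)
  # 1700 > 600 + 1000 excluded; 1999 <= 1000 + 1000 kept (inclusive
  # boundary); -5 anticipatory excluded; 1800 = 800 + 1000 kept exactly
  expect_equal(out2$tp_ms, c(1999, 1800))
  expect_equal(unname(attr(out2, "excluded")["window"]), 2)
})

test_that("trial tables round-trip through CSV and are validated on read", {
  s <- simulate_session(50, th, seed = 12)
  f <- tempfile(fileext = ".csv")
  write_trials(s, f)
  r <- read_trials(f)
  expect_equal(r$tp_ms, s$tp_ms)
  expect_equal(r$condition, s$condition)
  expect_equal(r$ts_ms, s$ts_ms)
  # off-support sample intervals accepted with a warning
  s$ts_ms[1] <- 650
  write_trials(s, f)
  expect_warning(read_trials(f), "650")
  # missing column is named
  bad <- s[, setdiff(names(s), "tp_ms")]
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_trials(f), "tp_ms")
  # non-numeric duration reported with its line
  s2 <- simulate_session(5, th, seed = 13)
  s2$tp_ms <- as.character(s2$tp_ms)
  s2$tp_ms[3] <- "oops"
  write.csv(s2, f, row.names = FALSE)
  expect_error(read_trials(f), "line.*3")
  # empty file: empty result with a warning
  writeLines("session,index,condition,ts_ms,tp_ms", f)
  expect_warning(r0 <- read_trials(f), "no trials")
  expect_equal(nrow(r0), 0L)
})
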