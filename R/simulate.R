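# Synthetic sessions of the 1-2-Go / 1-2-3-Go interval reproduction task.

# Vectorized estimator evaluation for simulated trials. tm2 is NA on
# one-measurement trials. Returns the internal estimate t_e per trial.
estimate_batch <- function(model, condition, tm1, tm2, params, prior, f1) {
  te <- numeric(length(tm1))
  one <- condition == "12G"
  if (any(one)) te[one] <- f1(tm1[one])
  two <- !one
  if (any(two)) {
    te[two] <- switch(model,
      bls = bls2_map(tm1[two], tm2[two], params$w_m, prior),
      bls_mem = blsmem_map(tm1[two], tm2[two], params$w_mem, params$w_m,
                           prior),
      lne = f1((tm1[two] + tm2[two]) / 2),
      ekf = {
        te1 <- f1(tm1[two])
        te1 + 0.5 * (f1(tm2[two] - te1 + prior$mean) - prior$mean)
      })
  }
  te
}

sim_f1 <- function(params, prior, tm_lo, tm_hi) {
  lo <- min(tm_lo, tm_lo - prior$t_max + prior$mean)
  hi <- max(tm_hi, tm_hi - prior$t_min + prior$mean)
  bls1_interp(params$w_m, prior, lo, hi)
}

#' Simulate one trial of the reproduction task
#'
#' Generative process of a single trial: with probability `gamma` the trial
#' is a lapse and `t_p` is drawn uniformly over the lapse range; otherwise
#' one (`"12G"`) or two (`"123G"`) measurements are drawn with scalar
#' noise, mapped to an estimate by the model's estimator, and `t_p` is
#' drawn as Gaussian with mean `t_e + b` and SD `w_p * t_e`. Negative
#' productions are redrawn. All latents are recorded.
#'
#' @param condition `"12G"` or `"123G"`.
#' @param t_s sample interval, ms.
#' @param params an [observer_params()].
#' @param prior an [interval_prior()].
#' @return one-row data frame with columns `condition`, `ts_ms`, `tp_ms`,
#'   `tm1_ms`, `tm2_ms`, `te_ms`, `is_lapse`.
#' @export
simulate_trial <- function(condition = c("12G", "123G"), t_s, params,
                           prior = interval_prior()) {
  condition <- match.arg(condition)
  sim_core(condition, t_s, params, prior)
}

# shared generative core, vectorized over trials
sim_core <- function(condition, ts, params, prior, f1 = NULL) {
  n <- length(ts)
  condition <- rep_len(condition, n)
  lapse <- runif(n) < params$gamma
  w1 <- ifelse(params$model == "bls_mem" & condition == "123G",
               params$w_mem %||% params$w_m, params$w_m)
  tm1 <- rnorm(n, ts, w1 * ts)
  tm2 <- ifelse(condition == "123G", rnorm(n, ts, params$w_m * ts), NA_real_)
  if (is.null(f1)) {
    rng <- range(c(tm1, tm2, (tm1 + ifelse(is.na(tm2), tm1, tm2)) / 2),
                 na.rm = TRUE)
    f1 <- sim_f1(params, prior, rng[1L], rng[2L])
  }
  te <- estimate_batch(params$model, condition, tm1, tm2, params, prior, f1)
  tp <- rnorm(n, te + params$b, params$w_p * te)
  # negative productions are physically impossible; redraw (rare for
  # realistic parameters, keeps the positive-side Gaussian shape intact)
  while (any(neg <- tp < 0)) {
    tp[neg] <- rnorm(sum(neg), te[neg] + params$b, params$w_p * te[neg])
  }
  if (any(lapse)) {
    tp[lapse] <- runif(sum(lapse), params$lapse_range[1L],
                       params$lapse_range[2L])
    tm1[lapse] <- tm2[lapse] <- te[lapse] <- NA_real_
  }
  data.frame(condition = condition, ts_ms = ts, tp_ms = tp, tm1_ms = tm1,
             tm2_ms = tm2, te_ms = te, is_lapse = lapse)
}

#' Simulate a session of interleaved 1-2-Go / 1-2-3-Go trials
#'
#' Draws `t_s` i.i.d. from the discrete prior support and the condition
#' i.i.d. with probability `condition_mix` of a 1-2-3-Go trial, then
#' generates every trial from the observer model. With
#' `with_staircase = TRUE` each trial is additionally scored against the
#' adaptive relative-error threshold: a response is correct when
#' `|t_p - t_s| / t_s <= k`, and `k` moves down by `step` after a correct
#' response and up by `step` after an incorrect one (one-up/one-down),
#' which equilibrates near 50% correct. The staircase only does
#' feedback bookkeeping; it never feeds back into the generative process.
#'
#' @param n_trials number of trials (> 0).
#' @param params an [observer_params()].
#' @param condition_mix fraction of 1-2-3-Go trials, default 0.5.
#' @param prior an [interval_prior()].
#' @param with_staircase score trials with the adaptive threshold?
#' @param session session identifier stored in the trial table.
#' @param seed optional integer seed; identical seeds give identical
#'   sessions.
#' @param staircase a [staircase_state()] giving the initial threshold and
#'   step.
#' @return data frame with one row per trial (columns `session`, `index`,
#'   `condition`, `ts_ms`, `tp_ms`, latents, and with the staircase also
#'   `correct` and `threshold_at_trial`), with the final
#'   `"staircase_state"` attached as attribute `"staircase"`.
#' @examples
#' th <- observer_params("bls", w_m = 0.1, w_p = 0.08)
#' s <- simulate_session(200, th, seed = 1, with_staircase = TRUE)
#' mean(s$correct)
#' @export
simulate_session <- function(n_trials, params, condition_mix = 0.5,
                             prior = interval_prior(),
                             with_staircase = FALSE, session = 1L,
                             seed = NULL, staircase = staircase_state()) {
  if (n_trials <= 0) stop("'n_trials' must be positive")
  if (condition_mix < 0 || condition_mix > 1)
    stop("'condition_mix' must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_trials)
  ts <- sample(prior$support, n, replace = TRUE)
  cond <- ifelse(runif(n) < condition_mix, "123G", "12G")
  # build one interpolator wide enough for both conditions
  w_hi <- max(params$w_m, params$w_mem %||% 0)
  f1 <- sim_f1(params, prior,
               min(prior$support) * (1 - 8 * w_hi),
               max(prior$support) * (1 + 8 * w_hi))
  out <- sim_core(cond, ts, params, prior, f1 = f1)
  out <- cbind(session = session, index = seq_len(n), out)
  if (with_staircase) {
    # same rule as staircase_update(), applied in a tight scalar loop
    k <- staircase$k
    step <- staircase$step
    rel_err <- abs(out$tp_ms - out$ts_ms) / out$ts_ms
    correct <- logical(n)
    thr <- numeric(n)
    for (i in seq_len(n)) {
      thr[i] <- k
      correct[i] <- rel_err[i] <= k
      k <- max(step, k + if (correct[i]) -step else step)
    }
    out$correct <- correct
    out$threshold_at_trial <- thr
    st <- structure(list(k = k, step = step,
                         history = data.frame(threshold = thr,
                                              correct = correct)),
                    class = "staircase_state")
    attr(out, "staircase") <- st
  }
  out
}

#' Adaptive correctness-threshold staircase
#'
#' One-up/one-down adjustment of the relative-error threshold used for
#' trial feedback: the threshold `k` decreases by `step` after a correct
#' response and increases by `step` after an incorrect one, and is floored
#' at `step` so it stays positive. The scheme equilibrates at about 50%
#' correct.
#'
#' @param k initial threshold (relative error), default 0.15 at the start
#'   of every session.
#' @param step threshold increment, default 0.001.
#' @return `staircase_state()` returns an object of class
#'   `"staircase_state"` with fields `k`, `step` and a `history` data frame
#'   of `(threshold, correct)` pairs.
#' @examples
#' st <- staircase_state()
#' staircase_update(st, correct = TRUE)$k   # 0.149
#' staircase_update(st, correct = FALSE)$k  # 0.151
#' @export
staircase_state <- function(k = 0.15, step = 0.001) {
  stopifnot(k > 0, step > 0)
  structure(list(k = k, step = step,
                 history = data.frame(threshold = numeric(0),
                                      correct = logical(0))),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state a `"staircase_state"`.
#' @param correct was the response within threshold?
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  k_new <- max(state$step,
               state$k + if (correct) -state$step else state$step)
  structure(list(k = k_new, step = state$step,
                 history = rbind(state$history,
                                 data.frame(threshold = state$k,
                                            correct = correct))),
            class = "staircase_state")
}

#' Trial exclusions
#'
#' Removes the warm-up trials at the start of each session (the first 99 by
#' default, during which subjects adapt to the prior) and any trial with an
#' anticipatory response (`t_p <= 0`) or a response later than
#' `window_ms` after the veridical interval (`t_p > t_s + window_ms`; the
#' boundary is kept, i.e. the window is inclusive).
#'
#' @param trials trial data frame with columns `session`, `index`,
#'   `ts_ms`, `tp_ms`.
#' @param warmup number of initial trials discarded per session.
#' @param window_ms response window beyond `t_s`, ms.
#' @return the filtered data frame, with attribute `"excluded"` giving the
#'   count removed by each rule.
#' @export
apply_exclusions <- function(trials, warmup = 99L, window_ms = 1000) {
  stopifnot(all(c("session", "index", "ts_ms", "tp_ms") %in% names(trials)))
  keep_warm <- rep(TRUE, nrow(trials))
  for (s in unique(trials$session)) {
    i <- which(trials$session == s)
    i <- i[order(trials$index[i])]
    keep_warm[i[seq_len(min(warmup, length(i)))]] <- FALSE
  }
  n_warm <- sum(!keep_warm)
  ok_win <- trials$tp_ms > 0 & trials$tp_ms <= trials$ts_ms + window_ms
  n_win <- sum(keep_warm & !ok_win)
  out <- trials[keep_warm & ok_win, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- c(warmup = n_warm, window = n_win)
  out
}
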