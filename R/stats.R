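# Behavioural summary statistics: BIAS^2, VAR, RMSE and related tests.

stats_one_condition <- function(ts, tp) {
  split_tp <- split(tp, ts)
  n_per <- lengths(split_tp)
  if (any(n_per < 2L))
    stop("every distinct t_s needs at least 2 trials (variance undefined)")
  ts_vals <- as.numeric(names(split_tp))
  means <- vapply(split_tp, mean, 0)
  vars <- vapply(split_tp, var, 0)   # unbiased, n - 1 denominator
  list(per_ts = data.frame(ts_ms = ts_vals, n = as.integer(n_per),
                           mean_tp = unname(means), var_tp = unname(vars)),
       bias_sq = mean((means - ts_vals)^2),
       var = mean(vars))
}

#' Bias, variance and RMSE of reproduction behaviour
#'
#' Overall accuracy decomposition over the distinct sample intervals:
#' `BIAS^2` is the mean squared deviation of the per-`t_s` mean production
#' from `t_s`, `VAR` the mean within-`t_s` variance of production (unbiased
#' `n - 1` denominator), and `RMSE = sqrt(BIAS^2 + VAR)`. Computed per
#' condition, after removing the fitted offset from every `t_p` and
#' excluding lapse-flagged trials.
#'
#' @param trials trial data frame with columns `condition`, `ts_ms`,
#'   `tp_ms`.
#' @param offset fitted production offset `b` subtracted from every `t_p`
#'   before the statistics are computed.
#' @param lapse optional logical vector of lapse flags (e.g. from
#'   [classify_lapse_trials()]); flagged trials are excluded.
#' @param source provenance tag, `"observed"` or `"model_expected"`.
#' @return data frame of class `"interval_stats"` with one row per
#'   condition (`bias_sq`, `var`, `rmse`, `n_distinct_ts`), per-`t_s`
#'   tables attached as attribute `"per_ts"`.
#' @examples
#' th <- observer_params("bls", w_m = 0.1, w_p = 0.08)
#' d <- simulate_session(2000, th, seed = 1)
#' bias_var_rmse(d)
#' @export
bias_var_rmse <- function(trials, offset = 0, lapse = NULL,
                          source = "observed") {
  check_trials(trials)
  if (!is.null(lapse)) {
    stopifnot(length(lapse) == nrow(trials))
    trials <- trials[!lapse, , drop = FALSE]
  }
  tp <- trials$tp_ms - offset
  conds <- unique(trials$condition)
  per_ts <- list()
  rows <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    sel <- trials$condition == conds[i]
    s <- stats_one_condition(trials$ts_ms[sel], tp[sel])
    per_ts[[conds[i]]] <- s$per_ts
    rows[[i]] <- data.frame(condition = conds[i], bias_sq = s$bias_sq,
                            var = s$var, rmse = sqrt(s$bias_sq + s$var),
                            n_distinct_ts = nrow(s$per_ts),
                            source = source)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_ts") <- per_ts
  class(out) <- c("interval_stats", "data.frame")
  out
}

#' Model-expected summary statistics by simulation
#'
#' Expected `BIAS^2`, `VAR` and `RMSE` of an observer model, obtained as
#' the mean of each statistic over repeated simulations of full datasets
#' with the per-`t_s` trial counts matched to the data (default 1000
#' repetitions). Simulations are run without the lapse term and with the
#' offset set to zero, matching how observed statistics are computed after
#' lapse exclusion and offset removal.
#'
#' @param params an [observer_params()] (its `gamma` and `b` are forced to
#'   0 for the simulation).
#' @param trial_counts_per_ts named integer vector of trial counts, one per
#'   prior-support interval (names are the `t_s` values in ms), or a single
#'   count applied to every support value.
#' @param condition `"12G"` or `"123G"`.
#' @param prior an [interval_prior()].
#' @param reps number of simulated datasets (>= 1).
#' @param seed optional integer seed.
#' @return an `"interval_stats"` row with `source = "model_expected"`.
#' @export
expected_model_stats <- function(params, trial_counts_per_ts,
                                 condition = c("12G", "123G"),
                                 prior = interval_prior(), reps = 1000L,
                                 seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (length(trial_counts_per_ts) == 1L && is.null(names(trial_counts_per_ts)))
    trial_counts_per_ts <- setNames(rep(trial_counts_per_ts,
                                        length(prior$support)),
                                    prior$support)
  ts_vals <- as.numeric(names(trial_counts_per_ts))
  counts <- as.integer(trial_counts_per_ts)
  p <- params
  p$gamma <- 0
  p$b <- 0
  ts_one <- rep(ts_vals, counts)
  ts_all <- rep(ts_one, reps)
  rep_id <- rep(seq_len(as.integer(reps)), each = length(ts_one))
  w_hi <- max(p$w_m, p$w_mem %||% 0)
  f1 <- sim_f1(p, prior, min(ts_vals) * (1 - 8 * w_hi),
               max(ts_vals) * (1 + 8 * w_hi))
  sim <- sim_core(condition, ts_all, p, prior, f1 = f1)
  ts_sorted <- sort(ts_vals)
  K <- length(ts_sorted)
  gi <- (rep_id - 1L) * K + match(sim$ts_ms, ts_sorted)
  n_g <- as.vector(rowsum(rep(1L, length(gi)), gi))
  sum_g <- as.vector(rowsum(sim$tp_ms, gi))
  sq_g <- as.vector(rowsum(sim$tp_ms^2, gi))
  mean_g <- sum_g / n_g
  var_g <- (sq_g - n_g * mean_g^2) / (n_g - 1L)
  ts_g <- rep(ts_sorted, times = reps)
  rep_g <- rep(seq_len(as.integer(reps)), each = K)
  bias_by_rep <- tapply((mean_g - ts_g)^2, rep_g, mean)
  var_by_rep <- tapply(var_g, rep_g, mean)
  bias_sq <- mean(bias_by_rep)
  v <- mean(var_by_rep)
  out <- data.frame(condition = condition, bias_sq = bias_sq, var = v,
                    rmse = sqrt(bias_sq + v),
                    n_distinct_ts = length(ts_vals),
                    source = "model_expected")
  class(out) <- c("interval_stats", "data.frame")
  out
}

#' Permutation test for an RMSE difference between conditions
#'
#' Tests whether the RMSE of two trial sets (the two task conditions of one
#' dataset, offset-removed and lapse-excluded) differ, by shuffling the
#' condition labels within each `t_s` stratum. The observed statistic is
#' `RMSE(A) - RMSE(B)`; the two-sided p-value is
#' `(1 + #{|null| >= |observed|}) / (1 + n_perm)`. Stratifying by `t_s`
#' preserves each condition's sample-interval composition under the null.
#'
#' @param trials_A,trials_B single-condition trial data frames (columns
#'   `ts_ms`, `tp_ms`).
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed.
#' @return list with `statistic` (observed RMSE difference, ms),
#'   `p_value`, and `n_perm`.
#' @export
rmse_permutation_test <- function(trials_A, trials_B, n_perm = 10000L,
                                  seed = NULL) {
  if (n_perm < 99L) stop("'n_perm' must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  rmse_of <- function(ts, tp) {
    s <- stats_one_condition(ts, tp)
    sqrt(s$bias_sq + s$var)
  }
  obs <- rmse_of(trials_A$ts_ms, trials_A$tp_ms) -
    rmse_of(trials_B$ts_ms, trials_B$tp_ms)
  ts_levels <- sort(unique(c(trials_A$ts_ms, trials_B$ts_ms)))
  pool <- lapply(ts_levels, function(s)
    c(trials_A$tp_ms[trials_A$ts_ms == s],
      trials_B$tp_ms[trials_B$ts_ms == s]))
  nA <- vapply(ts_levels, function(s) sum(trials_A$ts_ms == s), 0L)
  null <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    mA <- vA <- mB <- vB <- numeric(length(ts_levels))
    for (j in seq_along(ts_levels)) {
      x <- pool[[j]]
      ia <- sample.int(length(x), nA[j])
      a <- x[ia]
      b <- x[-ia]
      mA[j] <- mean(a)
      vA[j] <- var(a)
      mB[j] <- mean(b)
      vB[j] <- var(b)
    }
    null[p] <- sqrt(mean((mA - ts_levels)^2) + mean(vA)) -
      sqrt(mean((mB - ts_levels)^2) + mean(vB))
  }
  list(statistic = obs,
       p_value = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' RMSE normalized by the model-expected two-measurement RMSE
#'
#' Divides the observed RMSE of each condition by the model-expected RMSE
#' in the 1-2-3-Go condition, the normalization used to compare performance
#' across observers: a 1-2-3-Go ratio of 1 means the data achieve exactly
#' the improvement the fitted model expects from the second measurement.
#'
#' @param observed an `"interval_stats"` with rows for both conditions.
#' @param model_expected an `"interval_stats"` containing a `"123G"` row
#'   (typically from [expected_model_stats()]).
#' @return named numeric vector of ratios, one per observed condition.
#' @export
normalized_rmse <- function(observed, model_expected) {
  ref <- model_expected$rmse[model_expected$condition == "123G"]
  if (length(ref) != 1L || !is.finite(ref) || ref == 0)
    stop("'model_expected' must contain a 123G row with nonzero RMSE")
  setNames(observed$rmse / ref, observed$condition)
}
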