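#' Scalar-noise measurement likelihood
#'
#' Density of a noisy interval measurement `t_m` given the true sample
#' interval `t_s`, under the scalar property: Gaussian with mean `t_s` and
#' standard deviation `w * t_s`. Viewed as a function of `t_s` at fixed
#' `t_m` this family is skewed toward longer intervals and is not Gaussian,
#' which is what prevents simple moment-updating algorithms from being
#' optimal with more than one measurement.
#'
#' @param t_m measurement(s), ms; any real value.
#' @param t_s sample interval, ms (> 0).
#' @param w Weber fraction (> 0).
#' @return density per ms, vectorized over `t_m` and/or `t_s`.
#' @examples
#' scalar_likelihood(700, 800, 0.1)
#' @export
scalar_likelihood <- function(t_m, t_s, w) {
  if (any(!is.finite(t_s)) || any(t_s <= 0)) stop("'t_s' must be positive")
  if (any(!is.finite(w)) || any(w <= 0)) stop("'w' must be positive")
  dnorm(t_m, mean = t_s, sd = w * t_s)
}

# log-likelihood matrix, rows = measurements, cols = t_s grid, stabilized by
# subtracting the row maximum (scale cancels in posterior-mean ratios).
# Includes the 1/t_s prefactor of the scalar likelihood. With
# noise = "constant" the SD is the fixed 'sigma' instead of w * t_s (the
# Gaussian-noise control used to isolate consequences of scalar noise).
lik_mat_stab <- function(m, ts, w, noise = "scalar", sigma = NULL) {
  if (noise == "scalar") {
    logl <- -(outer(m, ts, "-"))^2 / (2 * w^2 * rep(ts^2, each = length(m))) -
      rep(log(ts), each = length(m))
  } else {
    logl <- -(outer(m, ts, "-"))^2 / (2 * sigma^2)
  }
  dim(logl) <- c(length(m), length(ts))
  mx <- apply(logl, 1L, max)
  exp(logl - mx)
}

#' Posterior over the sample interval
#'
#' Posterior density of `t_s` on a grid, given one or two measurements
#' under the scalar-noise likelihood and the continuous uniform prior. With
#' two measurements the posterior can be formed in one shot from the product
#' of the two likelihoods (`method = "batch"`) or sequentially, reusing the
#' one-measurement posterior as the prior for the second measurement
#' (`method = "recursive"`); the two forms are algebraically identical and
#' agree to numerical precision.
#'
#' @param t_s_grid evenly spaced grid covering `[t_min, t_max]`.
#' @param t_m1 first measurement, ms.
#' @param t_m2 optional second measurement, ms.
#' @param w_m measurement Weber fraction.
#' @param prior an [interval_prior()].
#' @param w_mem optional Weber fraction for the first measurement (memory
#'   variant); defaults to `w_m`.
#' @param method `"batch"` or `"recursive"` (two measurements only).
#' @return density vector over `t_s_grid`, normalized to integrate to 1 by
#'   the trapezoid rule on the grid; zero outside `[t_min, t_max]`.
#' @examples
#' pr <- interval_prior()
#' g <- seq(600, 1000, by = 2)
#' p <- posterior_interval(g, 750, w_m = 0.15, prior = pr)
#' @export
posterior_interval <- function(t_s_grid, t_m1, t_m2 = NULL, w_m, prior,
                               w_mem = w_m, method = c("batch", "recursive")) {
  method <- match.arg(method)
  if (min(t_s_grid) > prior$t_min || max(t_s_grid) < prior$t_max)
    stop("'t_s_grid' must cover the prior range [t_min, t_max]")
  inside <- t_s_grid >= prior$t_min & t_s_grid <= prior$t_max
  dens <- numeric(length(t_s_grid))
  ts_in <- t_s_grid[inside]
  if (is.null(t_m2)) {
    u <- drop(lik_mat_stab(t_m1, ts_in, w_mem))
  } else if (method == "batch") {
    u <- drop(lik_mat_stab(t_m1, ts_in, w_mem)) *
      drop(lik_mat_stab(t_m2, ts_in, w_m))
  } else {
    # sequential form: normalize after the first measurement, then multiply
    # in the second likelihood and renormalize (1/Z)
    p1 <- Recall(t_s_grid, t_m1, NULL, w_m = w_m, prior = prior,
                 w_mem = w_mem)[inside]
    u <- p1 * drop(lik_mat_stab(t_m2, ts_in, w_m))
  }
  dens[inside] <- u / trapz_int(ts_in, u)
  dens
}

# trapezoid integral on a (not necessarily uniform) grid
trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Bayes least-squares estimate from one measurement
#'
#' Posterior-mean estimate of the sample interval given a single
#' measurement under the scalar-noise likelihood and the continuous uniform
#' prior, computed by composite Simpson quadrature over the prior range.
#' The map is strictly increasing, bounded inside `(t_min, t_max)`, and
#' exhibits regression toward the prior mean: short measurements are pulled
#' up, long measurements pulled down. It is well defined for arguments far
#' outside the prior range (no clipping).
#'
#' @param t_m1 measurement(s), ms; vectorized.
#' @param w_m measurement Weber fraction (> 0).
#' @param prior an [interval_prior()].
#' @param n_nodes odd Simpson node count over the prior range.
#' @return estimate(s) in ms.
#' @examples
#' bls1_map(c(600, 800, 1000), w_m = 0.1, prior = interval_prior())
#' @export
bls1_map <- function(t_m1, w_m, prior, n_nodes = 201L) {
  if (!is.finite(w_m) || w_m <= 0) stop("'w_m' must be positive")
  g <- prior_ts_grid(prior, n_nodes)
  L <- lik_mat_stab(t_m1, g$ts, w_m)
  drop(L %*% (g$w * g$ts)) / drop(L %*% g$w)
}

#' Bayes least-squares estimate from two measurements
#'
#' Posterior-mean estimate given two conditionally independent measurements
#' of the same interval, each with scalar noise. The map is symmetric in
#' the two measurements and its iso-estimate contours in the
#' `(t_m1, t_m2)` plane are convex: the estimate is more strongly
#' influenced by the larger of the two measurements, a direct consequence
#' of scalar noise. Setting `noise = "constant"` replaces `w_m * t_s` by
#' the fixed `sigma` in both likelihoods, a control under which the
#' contours become straight lines `t_m1 + t_m2 = const`.
#'
#' @param t_m1,t_m2 measurement vectors (recycled to a common length).
#' @param w_m measurement Weber fraction.
#' @param prior an [interval_prior()].
#' @param n_nodes odd Simpson node count over the prior range.
#' @param noise `"scalar"` (default) or `"constant"`.
#' @param sigma fixed SD in ms, used only when `noise = "constant"`.
#' @return estimate(s) in ms.
#' @examples
#' bls2_map(650, 950, w_m = 0.12, prior = interval_prior())
#' @export
bls2_map <- function(t_m1, t_m2, w_m, prior, n_nodes = 201L,
                     noise = c("scalar", "constant"), sigma = NULL) {
  noise <- match.arg(noise)
  if (noise == "scalar" && (!is.finite(w_m) || w_m <= 0))
    stop("'w_m' must be positive")
  if (noise == "constant" && (is.null(sigma) || sigma <= 0))
    stop("'sigma' must be positive when noise = \"constant\"")
  n <- max(length(t_m1), length(t_m2))
  t_m1 <- rep_len(t_m1, n)
  t_m2 <- rep_len(t_m2, n)
  g <- prior_ts_grid(prior, n_nodes)
  est <- numeric(n)
  for (idx in chunk_indices(n, 20000L)) {
    L <- lik_mat_stab(t_m1[idx], g$ts, w_m, noise, sigma) *
      lik_mat_stab(t_m2[idx], g$ts, w_m, noise, sigma)
    est[idx] <- drop(L %*% (g$w * g$ts)) / drop(L %*% g$w)
  }
  est
}

# estimate on the tensor grid a x b (used by the trial likelihood);
# w1 applies to 'a' (first measurement), w2 to 'b'
bls2_tensor <- function(a, b, w1, w2, prior, n_nodes = 201L) {
  g <- prior_ts_grid(prior, n_nodes)
  A <- lik_mat_stab(a, g$ts, w1)
  B <- lik_mat_stab(b, g$ts, w2)
  num <- (A * rep(g$w * g$ts, each = length(a))) %*% t(B)
  den <- (A * rep(g$w, each = length(a))) %*% t(B)
  num / den
}

#' Memory-augmented two-measurement BLS estimate
#'
#' As [bls2_map()], but the first measurement carries its own Weber
#' fraction `w_mem`, modelling a noisier internal representation of the
#' first interval (memory degradation) or, when `w_mem < w_m`, a more
#' reliable first measurement. With `w_mem = w_m` it reduces exactly to
#' [bls2_map()]; as `w_mem` grows the first measurement loses influence and
#' the map approaches `bls1_map(t_m2)`.
#'
#' @inheritParams bls2_map
#' @param w_mem Weber fraction of the first measurement (> 0).
#' @return estimate(s) in ms.
#' @export
blsmem_map <- function(t_m1, t_m2, w_mem, w_m, prior, n_nodes = 201L) {
  if (!is.finite(w_mem) || w_mem <= 0) stop("'w_mem' must be positive")
  if (!is.finite(w_m) || w_m <= 0) stop("'w_m' must be positive")
  n <- max(length(t_m1), length(t_m2))
  t_m1 <- rep_len(t_m1, n)
  t_m2 <- rep_len(t_m2, n)
  g <- prior_ts_grid(prior, n_nodes)
  est <- numeric(n)
  for (idx in chunk_indices(n, 20000L)) {
    L <- lik_mat_stab(t_m1[idx], g$ts, w_mem) *
      lik_mat_stab(t_m2[idx], g$ts, w_m)
    est[idx] <- drop(L %*% (g$w * g$ts)) / drop(L %*% g$w)
  }
  est
}

chunk_indices <- function(n, size) {
  if (n == 0L) return(list())
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' One-measurement BLS lookup table
#'
#' Tabulates [bls1_map()] on an evenly spaced argument grid, for inspection
#' or export (e.g. `write.csv`). The same table backs the fast interpolator
#' used inside the EKF and LNE updaters and the trial likelihood.
#'
#' @param w_m measurement Weber fraction.
#' @param prior an [interval_prior()].
#' @param lo,hi argument range in ms; default spans 1200 ms either side of
#'   the prior mean, covering every innovation argument reachable at
#'   moderate noise levels.
#' @param spacing grid spacing in ms.
#' @param n_nodes odd Simpson node count.
#' @return data frame with columns `argument_ms`, `estimate_ms`.
#' @export
bls1_table <- function(w_m, prior, lo = prior$mean - 1200,
                       hi = prior$mean + 1200, spacing = 1, n_nodes = 201L) {
  x <- seq(lo, hi, by = spacing)
  data.frame(argument_ms = x,
             estimate_ms = bls1_map(x, w_m, prior, n_nodes))
}

# fast monotone-cubic interpolator for bls1_map over [lo, hi]
bls1_interp <- function(w_m, prior, lo, hi, spacing = 1, n_nodes = 201L) {
  lo <- floor(lo) - spacing
  hi <- ceiling(hi) + spacing
  x <- seq(lo, hi, by = spacing)
  splinefun(x, bls1_map(x, w_m, prior, n_nodes), method = "monoH.FC")
}

#' EKF estimator state and update
#'
#' The EKF-style updater keeps a point estimate `t_e` and its reliability,
#' expressed as a Weber fraction `w`. Before any measurement the estimate
#' is the prior mean and the reliability is infinite uncertainty
#' (`w = Inf`, handled symbolically so the first gain is exactly 1). Each
#' measurement `t_m` updates the state by
#' `t_e <- t_e + k * fstar(t_m - t_e)`, where the innovation nonlinearity
#' `fstar(x) = bls1_map(x + t_e0) - t_e0` is the one-measurement BLS map
#' recentred on the initial estimate `t_e0`, the gain is
#' `k = w^2 / (w^2 + w_m^2)`, and the reliability is propagated as
#' `w <- w * w_m / sqrt(w^2 + w_m^2)`, as in Gaussian cue combination.
#' After one measurement the EKF estimate is identical to the BLS model;
#' with two measurements it is suboptimal but retains curved iso-estimate
#' contours, and the result depends on measurement order.
#'
#' @param prior an [interval_prior()].
#' @return `ekf_init()` returns the pre-measurement state, a list of class
#'   `"ekf_state"` with fields `n`, `t_e`, `w`, `last_gain`, `last_error`.
#' @examples
#' pr <- interval_prior()
#' s <- ekf_init(pr)
#' s <- ekf_update(s, 700, w_m = 0.1, prior = pr)
#' s$t_e  # equals bls1_map(700, 0.1, pr)
#' @export
ekf_init <- function(prior) {
  structure(list(n = 0L, t_e = prior$mean, w = Inf, last_gain = NA_real_,
                 last_error = NA_real_),
            class = "ekf_state")
}

#' @rdname ekf_init
#' @param state an `"ekf_state"`.
#' @param t_m measurement, ms.
#' @param w_m measurement Weber fraction (> 0).
#' @param f1 optional precomputed interpolator for [bls1_map()] (a function
#'   of the measurement argument); supplied internally in hot loops.
#' @export
ekf_update <- function(state, t_m, w_m, prior, f1 = NULL) {
  if (!inherits(state, "ekf_state")) stop("'state' must be an ekf_state")
  if (!is.finite(w_m) || w_m <= 0) stop("'w_m' must be positive")
  if (is.null(f1)) f1 <- function(x) bls1_map(x, w_m, prior)
  if (is.infinite(state$w)) {
    # exact limit of the gain/reliability recursion at w = Inf
    k <- 1
    w_new <- w_m
  } else {
    k <- state$w^2 / (state$w^2 + w_m^2)
    w_new <- state$w * w_m / sqrt(state$w^2 + w_m^2)
  }
  x <- t_m - state$t_e
  fstar <- f1(x + prior$mean) - prior$mean
  structure(list(n = state$n + 1L, t_e = state$t_e + k * fstar, w = w_new,
                 last_gain = k, last_error = x),
            class = "ekf_state")
}

#' @rdname ekf_init
#' @param measurements ordered vector of measurements, ms (>= 1).
#' @export
ekf_estimate <- function(measurements, w_m, prior, f1 = NULL) {
  if (length(measurements) == 0L) stop("at least one measurement is required")
  if (is.null(f1)) f1 <- function(x) bls1_map(x, w_m, prior)
  s <- ekf_init(prior)
  for (m in measurements) s <- ekf_update(s, m, w_m, prior, f1 = f1)
  s$t_e
}

#' Linear-nonlinear estimate (LNE)
#'
#' Tracks the running average of the measurements with weights
#' `k_n = 1/n` (so `k_1 = 1` and `k_2 = 0.5`), then passes the final
#' average through the one-measurement BLS nonlinearity. Identical to
#' [bls1_map()] for one measurement; order-invariant; its iso-estimate
#' contours in the measurement plane are straight lines, since only the sum
#' of the measurements matters.
#'
#' @param measurements ordered vector of measurements, ms (>= 1).
#' @param w_m measurement Weber fraction of the BLS nonlinearity.
#' @param prior an [interval_prior()].
#' @param f1 optional precomputed [bls1_map()] interpolator.
#' @param details if `TRUE`, also return the running means and the gain
#'   applied at each step.
#' @return the estimate in ms, or (with `details`) a list with `estimate`,
#'   `running_mean` and `gains`.
#' @examples
#' lne_estimate(c(700, 900), w_m = 0.1, prior = interval_prior(),
#'              details = TRUE)
#' @export
lne_estimate <- function(measurements, w_m, prior, f1 = NULL,
                         details = FALSE) {
  n <- length(measurements)
  if (n == 0L) stop("at least one measurement is required")
  if (is.null(f1)) f1 <- function(x) bls1_map(x, w_m, prior)
  gains <- 1 / seq_len(n)
  tbar <- numeric(n)
  tbar[1L] <- measurements[1L]
  if (n > 1L) for (i in 2L:n)
    tbar[i] <- (1 - gains[i]) * tbar[i - 1L] + gains[i] * measurements[i]
  est <- f1(tbar[n])
  if (details) list(estimate = est, running_mean = tbar, gains = gains)
  else est
}

#' Production and lapse response densities
#'
#' `production_density()` is the density of the produced interval `t_p`
#' given the internal estimate `t_e`: Gaussian with mean `t_e + b` and SD
#' `w_p * t_e` (the offset shifts the mean only).
#' `response_mixture_density()` mixes it with a lapse component, uniform
#' over `lapse_range`, with weight `gamma`.
#'
#' @param t_p produced interval(s), ms.
#' @param t_e internal estimate, ms (> 0).
#' @param w_p production Weber fraction (> 0).
#' @param b constant offset, ms.
#' @return density per ms.
#' @export
production_density <- function(t_p, t_e, w_p, b = 0) {
  if (any(!is.finite(t_e)) || any(t_e <= 0)) stop("'t_e' must be positive")
  if (any(!is.finite(w_p)) || any(w_p <= 0)) stop("'w_p' must be positive")
  dnorm(t_p, mean = t_e + b, sd = w_p * t_e)
}

#' @rdname production_density
#' @param params an [observer_params()] (supplies `w_p`, `b`, `gamma`,
#'   `lapse_range`).
#' @export
response_mixture_density <- function(t_p, t_e, params) {
  lr <- params$lapse_range
  lapse <- ifelse(t_p >= lr[1L] & t_p <= lr[2L], 1 / diff(lr), 0)
  if (params$gamma >= 1) return(lapse)
  (1 - params$gamma) * production_density(t_p, t_e, params$w_p, params$b) +
    params$gamma * lapse
}
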