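# Trial likelihoods: p(t_p | t_s, Theta) for each model, by Simpson
# marginalization over the unobserved measurement(s).

# Build a fast bls1_map interpolator whose argument range covers every
# value the estimators can request for the given parameters and sample
# intervals: the measurement grids themselves (LNE midpoints lie inside),
# and the recentred EKF innovation arguments t_m2 - t_e1 + t_e0.
f1_for_params <- function(params, prior, quad, ts_values) {
  w_hi <- max(params$w_m, params$w_mem %||% 0)
  gmin <- min(ts_values * (1 - quad$span_sigmas * w_hi))
  gmax <- max(ts_values * (1 + quad$span_sigmas * w_hi))
  lo <- min(gmin, gmin - prior$t_max + prior$mean, prior$t_min)
  hi <- max(gmax, gmax - prior$t_min + prior$mean, prior$t_max)
  bls1_interp(params$w_m, prior, lo, hi, n_nodes = quad$n_nodes_ts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Estimator outputs and quadrature probability weights on the measurement
# grid(s) for one (condition, t_s) stratum. Returned flattened: the
# predictive density is then a weighted Gaussian mixture over 'te'.
stratum_components <- function(t_s, condition, params, prior, quad, f1) {
  if (condition == "12G") {
    mg <- measurement_grid(t_s, params$w_m, quad)
    return(list(te = f1(mg$nodes), w = mg$w))
  }
  w1 <- if (params$model == "bls_mem") params$w_mem else params$w_m
  g1 <- measurement_grid(t_s, w1, quad)
  g2 <- measurement_grid(t_s, params$w_m, quad)
  te <- switch(params$model,
    bls = bls2_tensor(g1$nodes, g2$nodes, params$w_m, params$w_m, prior,
                      quad$n_nodes_ts),
    bls_mem = bls2_tensor(g1$nodes, g2$nodes, params$w_mem, params$w_m,
                          prior, quad$n_nodes_ts),
    lne = {
      mid <- outer(g1$nodes, g2$nodes, "+") / 2
      matrix(f1(mid), nrow = length(g1$nodes))
    },
    ekf = {
      te1 <- f1(g1$nodes)
      # second gain is exactly 1/2: after one measurement the estimate's
      # Weber fraction equals w_m, so k2 = w_m^2 / (w_m^2 + w_m^2)
      x2 <- outer(-te1, g2$nodes, "+")
      te1 + 0.5 * (f1(x2 + prior$mean) - prior$mean)
    }
  )
  list(te = as.vector(te), w = as.vector(outer(g1$w, g2$w)))
}

# Collapse a large (te, weight) cloud onto a 1 ms te grid by linear mass
# splitting between neighbouring bins (preserves total mass and the first
# moment exactly). Relative density error stays below ~1e-4 (far tails)
# and well under that in the bulk — negligible against the quadrature and
# Monte-Carlo tolerances — while the mixture shrinks from n_tm^2
# components to a few hundred.
bin_components <- function(comp, spacing = 1) {
  if (length(comp$te) <= 512L) return(comp)
  lo <- floor(min(comp$te))
  grid <- seq(lo, ceiling(max(comp$te)) + spacing, by = spacing)
  pos <- (comp$te - lo) / spacing
  i0 <- floor(pos)
  frac <- pos - i0
  w_lo <- rowsum(comp$w * (1 - frac), i0)
  w_hi <- rowsum(comp$w * frac, i0 + 1L)
  w_all <- numeric(length(grid))
  w_all[as.integer(rownames(w_lo)) + 1L] <-
    w_all[as.integer(rownames(w_lo)) + 1L] + w_lo
  w_all[as.integer(rownames(w_hi)) + 1L] <-
    w_all[as.integer(rownames(w_hi)) + 1L] + w_hi
  keep <- w_all > 0
  list(te = grid[keep], w = w_all[keep])
}

#' Predictive density of the produced interval
#'
#' The trial likelihood `p(t_p | t_s, Theta)`: the lapse-augmented response
#' density marginalized over the unobserved measurement(s) by composite
#' Simpson quadrature. On 1-2-Go trials a single measurement grid centred
#' on `t_s` is used and all four models coincide; on 1-2-3-Go trials the
#' model's two-measurement estimator is evaluated on the tensor grid of
#' both measurements.
#'
#' @param t_p produced interval(s), ms; vectorized.
#' @param t_s sample interval, ms.
#' @param condition `"12G"` or `"123G"`.
#' @param params an [observer_params()].
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()].
#' @return density per ms at each `t_p`.
#' @examples
#' th <- observer_params("bls", w_m = 0.1, w_p = 0.08)
#' p_tp_given_ts(seq(600, 1000, 100), 800, "123G", th, interval_prior())
#' @export
p_tp_given_ts <- function(t_p, t_s, condition = c("12G", "123G"), params,
                          prior = interval_prior(), quad = quad_config()) {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "observer_params"),
            inherits(quad, "quad_config"))
  f1 <- f1_for_params(params, prior, quad, t_s)
  comp <- bin_components(stratum_components(t_s, condition, params, prior,
                                            quad, f1))
  mixture_density_cpp(t_p, comp$te, comp$w, params$w_p, params$b,
                      params$gamma, params$lapse_range[1L],
                      params$lapse_range[2L])
}

#' Dataset log-likelihood
#'
#' Sum over trials of the log predictive density of `t_p` given `t_s`, the
#' condition and the model parameters; trials are conditionally independent
#' given the parameters. The measurement-grid components are built once per
#' distinct `(condition, t_s)` stratum and shared by all trials of that
#' stratum.
#'
#' @param trials trial data frame with columns `condition`, `ts_ms`,
#'   `tp_ms` (as produced by [simulate_session()] or [read_trials()]).
#' @param params an [observer_params()].
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()]; with `cache_policy = "grid"` the density
#'   of each stratum is tabulated on a 1 ms grid over the lapse window and
#'   interpolated at the trial `t_p` values.
#' @return the log-likelihood in nats. If some trial has exactly zero
#'   density (possible when `gamma = 0` and `t_p` lies outside the
#'   numerical support of the response distribution) a warning lists the
#'   offending trials and `-Inf` is returned.
#' @export
dataset_loglik <- function(trials, params, prior = interval_prior(),
                           quad = quad_config()) {
  check_trials(trials)
  if (nrow(trials) == 0L) return(0)
  f1 <- f1_for_params(params, prior, quad, unique(trials$ts_ms))
  dens <- numeric(nrow(trials))
  key <- paste(trials$condition, trials$ts_ms)
  for (k in unique(key)) {
    idx <- which(key == k)
    comp <- bin_components(stratum_components(trials$ts_ms[idx[1L]],
                                              trials$condition[idx[1L]],
                                              params, prior, quad, f1))
    if (quad$cache_policy == "grid") {
      tp_grid <- seq(params$lapse_range[1L], params$lapse_range[2L], by = 1)
      tab <- mixture_density_cpp(tp_grid, comp$te, comp$w, params$w_p,
                                 params$b, params$gamma,
                                 params$lapse_range[1L],
                                 params$lapse_range[2L])
      sf <- splinefun(tp_grid, tab, method = "natural")
      dens[idx] <- pmax(sf(trials$tp_ms[idx]), 0)
    } else {
      dens[idx] <- mixture_density_cpp(trials$tp_ms[idx], comp$te, comp$w,
                                       params$w_p, params$b, params$gamma,
                                       params$lapse_range[1L],
                                       params$lapse_range[2L])
    }
  }
  if (any(dens == 0)) {
    warning(sprintf(
      "zero predictive density on trial(s) %s; returning -Inf",
      paste(head(which(dens == 0), 10L), collapse = ", ")))
    return(-Inf)
  }
  sum(log(dens))
}

check_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("'trials' must be a data frame")
  need <- c("condition", "ts_ms", "tp_ms")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("missing trial column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(trials$condition), c("12G", "123G"))
  if (length(bad))
    stop("unknown condition value(s): ", paste(bad, collapse = ", "))
  invisible(trials)
}
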