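#' Composite Simpson weights
#'
#' Weights of the composite Simpson rule on an evenly spaced grid with an
#' odd number of nodes, such that `sum(w * f(x))` approximates the integral
#' of `f` over the grid span.
#'
#' @param n odd number of nodes (>= 3).
#' @param h grid spacing.
#' @return numeric vector of length `n`.
#' @export
simpson_weights <- function(n, h) {
  n <- as.integer(n)
  if (n < 3L || n %% 2L == 0L) stop("'n' must be odd and >= 3")
  w <- rep(2, n)
  w[seq(2L, n - 1L, by = 2L)] <- 4
  w[c(1L, n)] <- 1
  w * h / 3
}

#' Quadrature settings for trial likelihoods
#'
#' Controls the Simpson grids used to marginalize the trial likelihood over
#' the unobserved measurement(s), and whether the predictive density
#' `p(t_p | t_s)` is evaluated directly at the observed `t_p` values or
#' tabulated once on a 1 ms `t_p` grid and interpolated.
#'
#' @param n_nodes_tm odd number of Simpson nodes per measurement dimension
#'   (>= 51). Each measurement grid is centred on `t_s` with half-width
#'   `span_sigmas * w_m * t_s`.
#' @param span_sigmas half-width of the measurement grids in units of the
#'   measurement SD (>= 4). Mass beyond the span is negligible at the
#'   default of 5 SDs; the grid is deliberately *not* truncated at zero,
#'   since the scalar-noise likelihood places no positivity constraint on
#'   the measurement.
#' @param n_nodes_tp number of `t_p` nodes used for normalization checks
#'   over the lapse window.
#' @param cache_policy `"direct"` evaluates the density at the exact trial
#'   `t_p` values; `"grid"` tabulates it on a 1 ms grid over the lapse
#'   window and interpolates with a cubic spline.
#' @param n_nodes_ts odd number of Simpson nodes for integrals over the
#'   prior range (estimator maps and posteriors).
#' @return An object of class `"quad_config"`.
#' @export
quad_config <- function(n_nodes_tm = 51L, span_sigmas = 5, n_nodes_tp = 2001L,
                        cache_policy = c("direct", "grid"),
                        n_nodes_ts = 201L) {
  n_nodes_tm <- as.integer(n_nodes_tm)
  n_nodes_ts <- as.integer(n_nodes_ts)
  if (n_nodes_tm < 51L || n_nodes_tm %% 2L == 0L)
    stop("'n_nodes_tm' must be odd and >= 51")
  if (span_sigmas < 4) stop("'span_sigmas' must be >= 4")
  if (n_nodes_ts < 3L || n_nodes_ts %% 2L == 0L)
    stop("'n_nodes_ts' must be odd and >= 3")
  structure(
    list(n_nodes_tm = n_nodes_tm, span_sigmas = as.numeric(span_sigmas),
         n_nodes_tp = as.integer(n_nodes_tp),
         cache_policy = match.arg(cache_policy), n_nodes_ts = n_nodes_ts),
    class = "quad_config"
  )
}

# Simpson grid for one measurement, centred on t_s with half-width
# span * w * t_s; returns nodes and probability weights (lambda * simpson)
measurement_grid <- function(t_s, w, quad) {
  half <- quad$span_sigmas * w * t_s
  g <- seq(t_s - half, t_s + half, length.out = quad$n_nodes_tm)
  sw <- simpson_weights(quad$n_nodes_tm, g[2L] - g[1L])
  list(nodes = g, w = dnorm(g, t_s, w * t_s) * sw)
}
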