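#' Sample-interval prior
#'
#' Describes the experimental distribution of sample intervals `t_s`. The
#' estimators integrate over the *continuous* uniform density on
#' `[t_min, t_max]` (the form in which the estimator integrals are written),
#' while the task simulator draws `t_s` from the *discrete* support, by
#' default five values evenly spaced between 600 and 1000 ms. The prior mean
#' also serves as the initial estimate of the EKF updater before any
#' measurement is made.
#'
#' @param t_min,t_max bounds of the continuous uniform prior, in ms.
#' @param support discrete sample-interval values used when simulating the
#'   task; all must lie in `[t_min, t_max]`.
#' @return An object of class `"interval_prior"` with fields `t_min`,
#'   `t_max`, `support` and `mean` (the midpoint of the continuous range).
#' @examples
#' pr <- interval_prior()
#' pr$support
#' @export
interval_prior <- function(t_min = 600, t_max = 1000,
                           support = seq(t_min, t_max, length.out = 5)) {
  stopifnot(is.numeric(t_min), is.numeric(t_max), length(t_min) == 1L,
            length(t_max) == 1L, is.numeric(support), length(support) >= 1L)
  if (!(t_min > 0 && t_min < t_max))
    stop("'t_min' must be positive and smaller than 't_max'")
  if (any(support < t_min | support > t_max))
    stop("every 'support' value must lie in [t_min, t_max]")
  structure(
    list(t_min = as.numeric(t_min), t_max = as.numeric(t_max),
         support = as.numeric(sort(support)),
         mean = (as.numeric(t_min) + as.numeric(t_max)) / 2),
    class = "interval_prior"
  )
}

#' @export
print.interval_prior <- function(x, ...) {
  cat("Sample-interval prior\n")
  cat(sprintf("  continuous uniform on [%g, %g] ms (mean %g ms)\n",
              x$t_min, x$t_max, x$mean))
  cat("  discrete support:", paste(x$support, collapse = ", "), "ms\n")
  invisible(x)
}

# internal: Simpson grid + weights over the continuous prior range
prior_ts_grid <- function(prior, n_nodes = 201L) {
  ts <- seq(prior$t_min, prior$t_max, length.out = n_nodes)
  list(ts = ts, w = simpson_weights(n_nodes, ts[2L] - ts[1L]))
}
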