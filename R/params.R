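#' Observer parameters
#'
#' Bundles the parameter vector Theta of an observer model: the measurement
#' and production Weber fractions, the constant production offset, the lapse
#' rate, and (for the memory-augmented BLS model) the Weber fraction of the
#' first measurement on two-measurement trials.
#'
#' @param model one of `"bls"`, `"bls_mem"`, `"lne"`, `"ekf"`.
#' @param w_m measurement Weber fraction (> 0); measurement noise SD is
#'   `w_m * t_s`.
#' @param w_p production Weber fraction (> 0); production noise SD is
#'   `w_p * t_e`.
#' @param b constant production offset in ms (shifts the mean of `t_p`, not
#'   its SD).
#' @param gamma lapse probability in `[0, 1]`; on lapse trials `t_p` is
#'   drawn uniformly over `lapse_range` irrespective of `t_s`.
#' @param w_mem Weber fraction of the first measurement on 1-2-3-Go trials
#'   (`bls_mem` only; > 0).
#' @param lapse_range the physically possible production window, default
#'   `c(0, 2000)` ms.
#' @return An object of class `"observer_params"`.
#' @examples
#' observer_params("ekf", w_m = 0.1, w_p = 0.08, b = 10, gamma = 0.02)
#' @export
observer_params <- function(model = c("bls", "bls_mem", "lne", "ekf"),
                            w_m, w_p, b = 0, gamma = 0, w_mem = NULL,
                            lapse_range = c(0, 2000)) {
  model <- match.arg(model)
  stopifnot(length(w_m) == 1L, length(w_p) == 1L, length(b) == 1L,
            length(gamma) == 1L, length(lapse_range) == 2L)
  if (!is.finite(w_m) || w_m <= 0) stop("'w_m' must be a positive number")
  if (!is.finite(w_p) || w_p <= 0) stop("'w_p' must be a positive number")
  if (!is.finite(gamma) || gamma < 0 || gamma > 1)
    stop("'gamma' must lie in [0, 1]")
  if (model == "bls_mem") {
    if (is.null(w_mem)) w_mem <- w_m
    if (!is.finite(w_mem) || w_mem <= 0) stop("'w_mem' must be positive")
  } else if (!is.null(w_mem)) {
    stop("'w_mem' is only meaningful for model = \"bls_mem\"")
  }
  if (lapse_range[1L] >= lapse_range[2L])
    stop("'lapse_range' must be an increasing pair")
  structure(
    list(model = model, w_m = as.numeric(w_m), w_p = as.numeric(w_p),
         b = as.numeric(b), gamma = as.numeric(gamma),
         w_mem = if (model == "bls_mem") as.numeric(w_mem) else NULL,
         lapse_range = as.numeric(lapse_range)),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf("Observer parameters [%s]\n", model_label(x$model)))
  cat(sprintf("  w_m = %.4g, w_p = %.4g, b = %.4g ms, gamma = %.4g\n",
              x$w_m, x$w_p, x$b, x$gamma))
  if (!is.null(x$w_mem)) cat(sprintf("  w_mem = %.4g\n", x$w_mem))
  invisible(x)
}

#' @export
as.double.observer_params <- function(x, ...) {
  v <- c(w_m = x$w_m, w_p = x$w_p, b = x$b, gamma = x$gamma)
  if (!is.null(x$w_mem)) v <- c(v, w_mem = x$w_mem)
  v
}

model_label <- function(model) {
  switch(model, bls = "BLS", bls_mem = "BLS_mem", lne = "LNE", ekf = "EKF",
         model)
}

# names of the free parameters of a model, in packing order
param_names <- function(model) {
  if (model == "bls_mem") c("w_m", "w_p", "b", "gamma", "w_mem")
  else c("w_m", "w_p", "b", "gamma")
}

params_from_vector <- function(theta, model, lapse_range = c(0, 2000)) {
  observer_params(model,
                  w_m = theta[["w_m"]], w_p = theta[["w_p"]],
                  b = theta[["b"]], gamma = theta[["gamma"]],
                  w_mem = if (model == "bls_mem") theta[["w_mem"]] else NULL,
                  lapse_range = lapse_range)
}
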