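# Maximum-likelihood fitting with leave-N-out cross-validation.

#' Fitting configuration
#'
#' @param test_block_size number of trials held out per fold (default 100).
#' @param restarts number of optimizer starts; the first uses `init` (or a
#'   neutral default), the rest are Latin-hypercube samples of a plausible
#'   parameter box.
#' @param fold_scheme `"contiguous"` holds out consecutive blocks in
#'   recorded trial order (deterministic); `"random"` permutes trials
#'   before blocking.
#' @param maxit,factr passed to [stats::optim()]'s L-BFGS-B.
#' @param bounds named list of per-parameter `(lower, upper)` box bounds.
#' @param seed optional integer seed controlling restart jitter and random
#'   fold assignment.
#' @return an object of class `"fit_control"`.
#' @export
fit_control <- function(test_block_size = 100L, restarts = 5L,
                        fold_scheme = c("contiguous", "random"),
                        maxit = 200L, factr = 1e7,
                        bounds = list(w_m = c(1e-3, 0.5),
                                      w_p = c(1e-3, 0.5),
                                      b = c(-300, 300),
                                      gamma = c(0, 0.3),
                                      w_mem = c(1e-3, 1)),
                        seed = NULL) {
  stopifnot(test_block_size >= 1, restarts >= 1)
  structure(list(test_block_size = as.integer(test_block_size),
                 restarts = as.integer(restarts),
                 fold_scheme = match.arg(fold_scheme),
                 maxit = as.integer(maxit), factr = factr, bounds = bounds,
                 seed = seed),
            class = "fit_control")
}

default_init <- c(w_m = 0.15, w_p = 0.1, b = 0, gamma = 0.02, w_mem = 0.3)

# box from which additional restarts are drawn (well inside the bounds)
init_box <- list(w_m = c(0.05, 0.3), w_p = c(0.03, 0.25), b = c(-60, 60),
                 gamma = c(0, 0.08), w_mem = c(0.05, 0.5))

#' Maximize the dataset log-likelihood over the observer parameters
#'
#' Bounded local optimization (L-BFGS-B) of [dataset_loglik()] from one or
#' more starting points: the first start is `init` (or a neutral default),
#' the remaining `restarts - 1` are Latin-hypercube draws from a plausible
#' parameter box. Returns the best fit across starts.
#'
#' @param trials trial data frame.
#' @param model one of `"bls"`, `"bls_mem"`, `"lne"`, `"ekf"`.
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()].
#' @param control a [fit_control()].
#' @param init optional starting [observer_params()] or named vector.
#' @return list with `params` (an [observer_params()]), `loglik`,
#'   `convergence` and a per-restart `trace` data frame.
#' @export
optimize_params <- function(trials, model, prior = interval_prior(),
                            quad = quad_config(), control = fit_control(),
                            init = NULL) {
  check_trials(trials)
  if (nrow(trials) == 0L) stop("'trials' must be non-empty")
  pn <- param_names(model)
  lower <- vapply(control$bounds[pn], `[`, 0, 1L)
  upper <- vapply(control$bounds[pn], `[`, 0, 2L)
  objective <- function(theta) {
    # finite-difference gradient probes may step just outside the box
    theta <- pmin(pmax(theta, lower), upper)
    names(theta) <- pn
    ll <- suppressWarnings(
      dataset_loglik(trials, params_from_vector(theta, model), prior, quad))
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- matrix(NA_real_, nrow = control$restarts, ncol = length(pn),
                   dimnames = list(NULL, pn))
  starts[1L, ] <- if (is.null(init)) default_init[pn]
                  else as.numeric(init)[pn]
  if (control$restarts > 1L) {
    u <- lhs::randomLHS(control$restarts - 1L, length(pn))
    for (j in seq_along(pn)) {
      bx <- init_box[[pn[j]]]
      starts[-1L, j] <- bx[1L] + u[, j] * (bx[2L] - bx[1L])
    }
  }
  starts[] <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                   rep(upper, each = nrow(starts)))
  pscale <- c(w_m = 0.1, w_p = 0.1, b = 50, gamma = 0.05, w_mem = 0.1)[pn]
  fits <- vector("list", control$restarts)
  for (r in seq_len(control$restarts)) {
    fits[[r]] <- tryCatch(
      optim(starts[r, ], objective, method = "L-BFGS-B", lower = lower,
            upper = upper,
            control = list(maxit = control$maxit, factr = control$factr,
                           parscale = pscale)),
      error = function(e) e)
  }
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok))
    stop("optimization failed on all restarts; first error: ",
         conditionMessage(fits[[1L]]))
  vals <- vapply(fits[ok], `[[`, 0, "value")
  best <- fits[ok][[which.min(vals)]]
  theta <- setNames(best$par, pn)
  list(params = params_from_vector(theta, model), loglik = -best$value,
       convergence = best$convergence,
       trace = data.frame(restart = which(ok),
                          loglik = -vals,
                          converged = vapply(fits[ok], `[[`, 0L,
                                             "convergence") == 0L))
}

#' Fit an observer model by cross-validated maximum likelihood
#'
#' The main model-fitting entry point. Trials are partitioned into test
#' blocks of `test_block_size`; for each fold the model is fit by maximum
#' likelihood on the complement and the held-out log-likelihood of the test
#' block is recorded; the final parameter estimate is the arithmetic mean
#' of the per-fold maximum-likelihood parameters. Both task conditions
#' share one `(w_m, w_p, b, gamma)` (plus `w_mem` for `"bls_mem"`, which
#' acts only on the first measurement of 1-2-3-Go trials).
#'
#' @param data trial data frame with columns `condition`, `ts_ms`, `tp_ms`
#'   (see [simulate_session()], [read_trials()]).
#' @param model one of `"bls"`, `"bls_mem"`, `"lne"`, `"ekf"`.
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()].
#' @param control a [fit_control()].
#' @param init optional starting parameters for every fold.
#' @return an object of class `"observer_fit"`; see [coef.observer_fit()],
#'   [summary.observer_fit()], [predict.observer_fit()],
#'   [simulate.observer_fit()], [compare_observers()].
#' @examples
#' \donttest{
#' th <- observer_params("bls", w_m = 0.1, w_p = 0.08, gamma = 0.02)
#' d <- simulate_session(400, th, seed = 1)
#' fit <- fit_observer(d, "bls",
#'                     control = fit_control(test_block_size = 200,
#'                                           restarts = 1))
#' coef(fit)
#' }
#' @export
fit_observer <- function(data, model = c("bls", "bls_mem", "lne", "ekf"),
                         prior = interval_prior(), quad = quad_config(),
                         control = fit_control(), init = NULL) {
  model <- match.arg(model)
  check_trials(data)
  n <- nrow(data)
  if (!is.null(control$seed)) set.seed(control$seed)
  block <- control$test_block_size
  if (n < 2L * block) {
    warning("fewer than two test blocks available; ",
            "fitting a single fold on the full data")
    fold_id <- rep(1L, n)
    single <- TRUE
  } else {
    nb <- n %/% block
    fold_id <- pmin(ceiling(seq_len(n) / block), nb)
    if (control$fold_scheme == "random") fold_id <- sample(fold_id)
    single <- FALSE
  }
  folds <- sort(unique(fold_id))
  pn <- param_names(model)
  per_fold <- matrix(NA_real_, nrow = length(folds), ncol = length(pn),
                     dimnames = list(NULL, pn))
  test_ll <- train_ll <- numeric(length(folds))
  for (f in seq_along(folds)) {
    test <- fold_id == folds[f]
    train <- if (single) test else !test
    opt <- optimize_params(data[train, , drop = FALSE], model, prior, quad,
                           control, init = init)
    per_fold[f, ] <- as.numeric(opt$params)[pn]
    train_ll[f] <- opt$loglik
    test_ll[f] <- dataset_loglik(data[test, , drop = FALSE], opt$params,
                                 prior, quad)
  }
  avg <- colMeans(per_fold)
  structure(
    list(model = model, params = params_from_vector(avg, model),
         per_fold_params = per_fold, per_fold_test_loglik = test_ll,
         per_fold_train_loglik = train_ll, fold_id = fold_id,
         n_trials = n, data = data, prior = prior, quad = quad,
         control = control, call = match.call()),
    class = "observer_fit")
}

#' Identify lapse trials
#'
#' Flags trial `i` as a lapse when the lapse branch of the response mixture
#' is more likely than the non-lapse branch:
#' `gamma * p(t_p | lapse) > (1 - gamma) * p_nonlapse(t_p | t_s, Theta)`,
#' where the non-lapse density is the measurement-marginalized predictive
#' density with the lapse term removed (the internal estimate is latent, so
#' the comparison is made at the level of observables).
#'
#' @param trials trial data frame.
#' @param params fitted [observer_params()].
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()].
#' @return logical vector, one flag per trial; all `FALSE` when
#'   `gamma = 0`.
#' @export
classify_lapse_trials <- function(trials, params, prior = interval_prior(),
                                  quad = quad_config()) {
  check_trials(trials)
  if (params$gamma <= 0) return(rep(FALSE, nrow(trials)))
  dens_non <- numeric(nrow(trials))
  f1 <- f1_for_params(params, prior, quad, unique(trials$ts_ms))
  key <- paste(trials$condition, trials$ts_ms)
  for (k in unique(key)) {
    idx <- which(key == k)
    comp <- bin_components(stratum_components(trials$ts_ms[idx[1L]],
                                              trials$condition[idx[1L]],
                                              params, prior, quad, f1))
    dens_non[idx] <- mixture_density_cpp(trials$tp_ms[idx], comp$te,
                                         comp$w, params$w_p, params$b, 0,
                                         params$lapse_range[1L],
                                         params$lapse_range[2L])
  }
  lr <- params$lapse_range
  dens_lapse <- ifelse(trials$tp_ms >= lr[1L] & trials$tp_ms <= lr[2L],
                       1 / diff(lr), 0)
  params$gamma * dens_lapse > (1 - params$gamma) * dens_non
}

#' Held-out model comparison against a reference fit
#'
#' Per-fold log-likelihood ratios of one or more candidate fits against a
#' reference fit (conventionally the BLS fit), evaluated on the held-out
#' test blocks. All fits must share the same data and fold partition.
#'
#' @param ... candidate `"observer_fit"` objects.
#' @param reference the reference `"observer_fit"`.
#' @return data frame of class `"observer_comparison"` with one row per
#'   candidate: `model`, `mean_llr` (mean per-fold held-out log-likelihood
#'   ratio), `se_llr` (standard error across folds), `n_folds`; per-fold
#'   ratios are attached as attribute `"per_fold"`.
#' @export
compare_observers <- function(..., reference) {
  cands <- list(...)
  if (length(cands) == 1L && is.list(cands[[1L]]) &&
      !inherits(cands[[1L]], "observer_fit"))
    cands <- cands[[1L]]
  stopifnot(length(cands) >= 1L, inherits(reference, "observer_fit"))
  per_fold <- list()
  rows <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fit <- cands[[i]]
    stopifnot(inherits(fit, "observer_fit"))
    if (fit$n_trials != reference$n_trials ||
        !identical(fit$fold_id, reference$fold_id))
      stop("candidate and reference fits use different fold partitions")
    llr <- fit$per_fold_test_loglik - reference$per_fold_test_loglik
    per_fold[[model_label(fit$model)]] <- llr
    rows[[i]] <- data.frame(
      model = model_label(fit$model), mean_llr = mean(llr),
      se_llr = if (length(llr) > 1L) sd(llr) / sqrt(length(llr))
               else NA_real_,
      n_folds = length(llr))
  }
  out <- do.call(rbind, rows)
  attr(out, "per_fold") <- per_fold
  attr(out, "reference") <- model_label(reference$model)
  class(out) <- c("observer_comparison", "data.frame")
  out
}

#' @export
print.observer_comparison <- function(x, ...) {
  cat(sprintf("Held-out log-likelihood ratios vs %s (per fold mean, SE)\n",
              attr(x, "reference")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
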