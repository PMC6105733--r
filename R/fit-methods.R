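# S3 methods for "observer_fit".

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("Observer model fit [%s]\n", model_label(x$model)))
  cat(sprintf("  %d trials, %d fold(s) (%s blocks of %d)\n", x$n_trials,
              length(x$per_fold_test_loglik), x$control$fold_scheme,
              x$control$test_block_size))
  cat("  averaged ML parameters:\n")
  th <- as.numeric(x$params)
  cat("   ", paste(sprintf("%s = %.4g", names(th), th), collapse = ", "),
      "\n")
  cat(sprintf("  mean held-out log-likelihood per fold: %.2f nats\n",
              mean(x$per_fold_test_loglik)))
  invisible(x)
}

#' Summarize an observer fit
#'
#' @param object an `"observer_fit"`.
#' @param ... unused.
#' @return list of class `"summary.observer_fit"` with the per-fold
#'   parameter table, averaged parameters and held-out log-likelihoods.
#' @export
summary.observer_fit <- function(object, ...) {
  structure(
    list(model = object$model,
         per_fold = cbind(object$per_fold_params,
                          test_loglik = object$per_fold_test_loglik,
                          train_loglik = object$per_fold_train_loglik),
         params = as.numeric(object$params),
         n_trials = object$n_trials,
         mean_test_loglik = mean(object$per_fold_test_loglik)),
    class = "summary.observer_fit")
}

#' @export
print.summary.observer_fit <- function(x, ...) {
  cat(sprintf("Observer model fit [%s], %d trials\n", model_label(x$model),
              x$n_trials))
  cat("\nPer-fold maximum-likelihood parameters:\n")
  print(round(x$per_fold, 4))
  cat("\nAveraged parameters:\n")
  print(round(x$params, 5))
  cat(sprintf("\nMean held-out log-likelihood per fold: %.2f nats\n",
              x$mean_test_loglik))
  invisible(x)
}

#' @export
coef.observer_fit <- function(object, ...) as.numeric(object$params)

#' @export
logLik.observer_fit <- function(object, ...) {
  ll <- dataset_loglik(object$data, object$params, object$prior,
                       object$quad)
  structure(ll, df = length(as.numeric(object$params)),
            nobs = object$n_trials, class = "logLik")
}

#' Predicted production-interval moments
#'
#' Mean and standard deviation of the predictive distribution of `t_p` for
#' each `(condition, t_s)` combination, under the fitted parameters
#' (including the lapse component).
#'
#' @param object an `"observer_fit"`.
#' @param newdata optional data frame with columns `condition` and `ts_ms`;
#'   defaults to the distinct combinations in the fitted data.
#' @param ... unused.
#' @return data frame with columns `condition`, `ts_ms`, `mean_tp`,
#'   `sd_tp`.
#' @export
predict.observer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    newdata <- unique(object$data[c("condition", "ts_ms")])
    newdata <- newdata[order(newdata$condition, newdata$ts_ms), ,
                       drop = FALSE]
  }
  p <- object$params
  f1 <- f1_for_params(p, object$prior, object$quad, unique(newdata$ts_ms))
  lr <- p$lapse_range
  out <- newdata
  out$mean_tp <- out$sd_tp <- NA_real_
  for (i in seq_len(nrow(newdata))) {
    comp <- stratum_components(newdata$ts_ms[i], newdata$condition[i], p,
                               object$prior, object$quad, f1)
    w <- comp$w / sum(comp$w)
    m1 <- sum(w * (comp$te + p$b))
    m2 <- sum(w * ((comp$te + p$b)^2 + (p$w_p * comp$te)^2))
    lap_m1 <- mean(lr)
    lap_m2 <- (lr[2L]^3 - lr[1L]^3) / (3 * diff(lr))
    mu <- (1 - p$gamma) * m1 + p$gamma * lap_m1
    ex2 <- (1 - p$gamma) * m2 + p$gamma * lap_m2
    out$mean_tp[i] <- mu
    out$sd_tp[i] <- sqrt(max(ex2 - mu^2, 0))
  }
  rownames(out) <- NULL
  out
}

#' @export
residuals.observer_fit <- function(object, ...) {
  pred <- predict(object)
  key <- paste(object$data$condition, object$data$ts_ms)
  pkey <- paste(pred$condition, pred$ts_ms)
  object$data$tp_ms - pred$mean_tp[match(key, pkey)]
}

#' Simulate sessions from a fitted observer
#'
#' @param object an `"observer_fit"`.
#' @param nsim number of sessions.
#' @param seed optional integer seed.
#' @param n_trials trials per session; defaults to the fitted dataset
#'   size.
#' @param ... passed to [simulate_session()].
#' @return a trial data frame (`nsim = 1`) or a list of them.
#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL,
                                  n_trials = object$n_trials, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(s)
    simulate_session(n_trials, object$params, prior = object$prior,
                     session = s, ...))
  if (nsim == 1L) out[[1L]] else out
}
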