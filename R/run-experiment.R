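# End-to-end reproducibility harness: simulate -> exclude -> fit -> compare
# -> summarize, with every artefact written to disk.

#' Run a full synthetic-experiment pipeline
#'
#' Simulates a session from a generating observer, applies the standard
#' trial exclusions, fits the requested models by cross-validated maximum
#' likelihood, compares them to the BLS reference on held-out
#' log-likelihood, and computes observed summary statistics. All outputs
#' (trial CSV, per-model fit JSONs, comparison table, statistics, resolved
#' configuration) are written to `out_dir` and the whole run is
#' reproducible from `seed`.
#'
#' @param gen_params generating [observer_params()].
#' @param n_trials number of simulated trials.
#' @param models character vector of models to fit (must include `"bls"`,
#'   the comparison reference).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param seed integer seed governing simulation, fold jitter and restarts.
#' @param condition_mix fraction of 1-2-3-Go trials.
#' @param warmup,window_ms passed to [apply_exclusions()].
#' @param with_staircase simulate the adaptive feedback staircase?
#' @param prior an [interval_prior()].
#' @param quad a [quad_config()].
#' @param control a [fit_control()].
#' @return (invisibly) a list with `trials`, `fits`, `comparison`,
#'   `stats`, `excluded` and the resolved `config`.
#' @export
run_experiment <- function(gen_params, n_trials = 1000L,
                           models = c("bls", "bls_mem", "lne", "ekf"),
                           out_dir = NULL, seed = 1L, condition_mix = 0.5,
                           warmup = 99L, window_ms = 1000,
                           with_staircase = FALSE,
                           prior = interval_prior(), quad = quad_config(),
                           control = fit_control()) {
  if (!"bls" %in% models) stop("'models' must include the \"bls\" reference")
  config <- list(model = gen_params$model,
                 gen_params = as.numeric(gen_params), n_trials = n_trials,
                 models = models, seed = seed,
                 condition_mix = condition_mix, warmup = warmup,
                 window_ms = window_ms, with_staircase = with_staircase,
                 prior = unclass(prior),
                 quad = unclass(quad),
                 control = unclass(control)[c("test_block_size", "restarts",
                                              "fold_scheme", "maxit")])
  stage <- "simulate"
  res <- tryCatch({
    raw <- simulate_session(n_trials, gen_params,
                            condition_mix = condition_mix, prior = prior,
                            with_staircase = with_staircase, seed = seed)
    stage <- "exclude"
    trials <- apply_exclusions(raw, warmup = warmup, window_ms = window_ms)
    stage <- "fit"
    fits <- list()
    for (m in models) {
      ctl <- control
      ctl$seed <- seed + match(m, models)
      fits[[m]] <- fit_observer(trials, m, prior = prior, quad = quad,
                                control = ctl)
    }
    stage <- "compare"
    cand <- fits[setdiff(models, "bls")]
    comparison <- if (length(cand))
      compare_observers(cand, reference = fits[["bls"]]) else NULL
    stage <- "stats"
    lapse <- classify_lapse_trials(trials, fits[["bls"]]$params, prior,
                                   quad)
    stats <- bias_var_rmse(trials, offset = fits[["bls"]]$params$b,
                           lapse = lapse)
    list(trials = trials, fits = fits, comparison = comparison,
         stats = stats, excluded = attr(trials, "excluded"),
         staircase = attr(raw, "staircase"), config = config)
  }, error = function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(res$trials, file.path(out_dir, "trials.csv"))
    if (!is.null(res$staircase))
      write.csv(res$staircase$history, file.path(out_dir, "staircase.csv"),
                row.names = FALSE)
    for (m in names(res$fits))
      jsonlite::write_json(fit_as_list(res$fits[[m]]),
                           file.path(out_dir, paste0("fit_", m, ".json")),
                           auto_unbox = TRUE, digits = 9)
    if (!is.null(res$comparison))
      write.csv(res$comparison, file.path(out_dir, "comparison.csv"),
                row.names = FALSE)
    write.csv(res$stats, file.path(out_dir, "summary_stats.csv"),
              row.names = FALSE)
    jsonlite::write_json(config, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = 9)
  }
  invisible(res)
}

# serializable view of an observer_fit
fit_as_list <- function(fit) {
  list(model = fit$model, averaged_params = as.list(as.numeric(fit$params)),
       per_fold_params = apply(fit$per_fold_params, 1L, as.list,
                               simplify = FALSE),
       per_fold_test_loglik = fit$per_fold_test_loglik,
       per_fold_train_loglik = fit$per_fold_train_loglik,
       n_trials = fit$n_trials,
       test_block_size = fit$control$test_block_size,
       fold_scheme = fit$control$fold_scheme)
}
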