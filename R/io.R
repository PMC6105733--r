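# Trial-table readers and writers (CSV/TSV).

#' Read and write trial tables
#'
#' `read_trials()` reads a CSV or TSV trial table with required columns
#' `session`, `index`, `condition`, `ts_ms`, `tp_ms` (extra columns such as
#' simulated latents are kept). Condition tokens `12G`/`123G` are accepted
#' case-insensitively. Sample intervals outside the default prior support
#' are accepted with a warning, since real data may come from a different
#' prior. `write_trials()` writes the complementary format.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param prior an [interval_prior()] used only to warn about off-support
#'   `ts_ms` values.
#' @return `read_trials()`: a validated trial data frame.
#' @export
read_trials <- function(path, dialect = c("csv", "tsv"),
                        prior = interval_prior()) {
  dialect <- match.arg(dialect)
  raw <- tryCatch(
    if (dialect == "csv") read.csv(path, stringsAsFactors = FALSE)
    else read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop("could not read '", path, "': ",
                             conditionMessage(e)))
  if (nrow(raw) == 0L) {
    warning("'", path, "' contains no trials")
    return(raw)
  }
  need <- c("session", "index", "condition", "ts_ms", "tp_ms")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("index", "ts_ms", "tp_ms")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (any(bad <- is.na(v) & !is.na(raw[[col]])))
      stop(sprintf("non-numeric '%s' on data line(s) %s", col,
                   paste(which(bad), collapse = ", ")))
    raw[[col]] <- v
  }
  raw$condition <- toupper(trimws(raw$condition))
  bad <- !raw$condition %in% c("12G", "123G")
  if (any(bad))
    stop("unrecognized condition on data line(s) ",
         paste(which(bad), collapse = ", "))
  off <- setdiff(unique(raw$ts_ms), prior$support)
  if (length(off))
    warning("sample interval(s) outside the prior support: ",
            paste(off, collapse = ", "))
  raw
}

#' @rdname read_trials
#' @param trials trial data frame.
#' @export
write_trials <- function(trials, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  check_trials(trials)
  if (dialect == "csv") write.csv(trials, path, row.names = FALSE)
  else utils::write.table(trials, path, sep = "\t", row.names = FALSE,
                          quote = FALSE)
  invisible(path)
}
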