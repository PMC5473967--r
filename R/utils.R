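#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Validation error with a consistent class so tests can target it.
dt_stop <- function(..., class = "dualtrans_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

dt_config_stop <- function(field, why) {
  dt_stop("invalid configuration field '", field, "': ", why,
          class = c("dualtrans_config_error", "dualtrans_error"))
}

# Filtering-step log line: n in / n out, mirrors the reporting style of
# ribosome-profiling studies. Silenced via options(dualtrans.verbose = FALSE).
dt_log <- function(step, n_in, n_out, extra = NULL) {
  if (isTRUE(getOption("dualtrans.verbose", FALSE))) {
    msg <- sprintf("[dualtrans] %s: %d in, %d out", step, n_in, n_out)
    if (!is.null(extra)) msg <- paste0(msg, " (", extra, ")")
    message(msg)
  }
  invisible(NULL)
}

# Wrap a phase difference (hours) into (-12, 12]; the boundary maps to +12.
wrap_phase_diff <- function(d, period = 24) {
  half <- period / 2
  d <- d %% period
  d[d > half] <- d[d > half] - period
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
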