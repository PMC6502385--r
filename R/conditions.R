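# Classed conditions so callers (and the CLI) can distinguish bad input from
# numerical breakdown.

stop_validation <- function(...) {
  stop(structure(
    class = c("vitcclock_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_numerical <- function(..., diagnostics = NULL) {
  stop(structure(
    class = c("vitcclock_numerical_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1), diagnostics = diagnostics)
  ))
}

warn_regime <- function(...) {
  warning(structure(
    class = c("vitcclock_regime_warning", "warning", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_validation("`", name, "` must be a finite numeric of length ", len)
  if (strict && any(x <= lower))
    stop_validation("`", name, "` must be > ", lower, " (got ", format(x), ")")
  if (!strict && any(x < lower))
    stop_validation("`", name, "` must be >= ", lower, " (got ", format(x), ")")
  invisible(x)
}
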