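#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and tests) can distinguish user error from
# degenerate data. All package errors inherit "msncm_error".
msncm_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "msncm_error")))
}

stop_malformed <- function(msg) msncm_stop(msg, "msncm_malformed_data")
stop_parameter <- function(msg) msncm_stop(msg, "msncm_parameter_error")
stop_degenerate <- function(msg) msncm_stop(msg, "msncm_degenerate_input")

is_count_like <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
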