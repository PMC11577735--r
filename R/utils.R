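# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# p-values are clamped here before any -log10 transform; 1e-300 keeps the
# transform finite in double precision.
.P_FLOOR <- 1e-300

clamp_p <- function(p) pmax(p, .P_FLOOR)

# Lightweight structured logging: messages prefixed with a component tag so
# pipeline runs can be audited from the condition stream.
constru_log <- function(component, fmt, ...) {
  message(sprintf("[%s] %s", component, sprintf(fmt, ...)))
}

stop_constru <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
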