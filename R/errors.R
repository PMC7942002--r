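# Structured error conditions. Every package error carries class "dq_error"
# plus a code-specific class "dq_<code>_error" and a machine-readable $code,
# so callers (and the fail-soft executor) can dispatch without string matching.

dq_error <- function(code, msg, ...) {
  stop(errorCondition(
    msg,
    code = code,
    ...,
    class = c(paste0("dq_", tolower(code), "_error"), "dq_error", "error")
  ))
}

dq_assert <- function(cond, code, msg) {
  if (!isTRUE(cond)) dq_error(code, msg)
  invisible(TRUE)
}

#' @keywords internal
"_PACKAGE"
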