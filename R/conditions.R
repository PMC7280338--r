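# Condition constructors shared across the package. Every user-facing failure
# carries a class so the CLI can map it to an exit code without string matching.

wg_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "wg_error")))
}

wg_usage_error      <- function(msg, ...) wg_error(msg, "wg_usage_error", ...)
wg_missing_input    <- function(msg, ...) wg_error(msg, "wg_missing_input", ...)
wg_parse_error      <- function(msg, ...) wg_error(msg, "wg_parse_error", ...)
wg_validation_error <- function(msg, ...) wg_error(msg, "wg_validation_error", ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical, deterministic number formatting for text exports
.num_str <- function(x) trimws(formatC(x, digits = 15, format = "g"))
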