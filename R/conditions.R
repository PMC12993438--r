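# Condition helpers. Every schemakit error carries a specific condition class
# (e.g. "schemakit_unknown_prefix") below the umbrella class "schemakit_error",
# so callers can test failure modes with expect_error(..., class = ...).

sk_stop <- function(message, class, data = list()) {
  cond <- structure(
    class = c(paste0("schemakit_", class), "schemakit_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

sk_warn <- function(message, class = "warning") {
  warning(warningCondition(message, class = c(paste0("schemakit_", class), "schemakit_warning")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# TRUE only for a length-1, non-NA character string
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# logical tri-state: NA means "unset" (inherit / default later)
is_set <- function(x) !is.null(x) && !(is.logical(x) && length(x) == 1L && is.na(x))

# canonical empty container: drop a zero-length names attribute so that
# structural equality does not depend on how an empty list was built
norm_list <- function(x) {
  if (is.null(x)) return(list())
  if (length(x) == 0L) return(list())
  x
}
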