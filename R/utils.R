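# internal validation helpers

abort_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

abort_format <- function(msg) {
  stop(sprintf("format error: %s", msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) < 1L || any(is.na(x)) || any(x < 0) || any(x > 1))
    abort_config(field, "must be a fraction in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) < 1L || any(is.na(x)) || any(x < min) ||
      any(x != floor(x)))
    abort_config(field, sprintf("must be an integer count >= %d", min))
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    abort_config(field, "must be a positive real")
  invisible(x)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stable deterministic ordering used by all writers
order_by <- function(df, cols) {
  df[do.call(order, lapply(cols, function(cl) df[[cl]])), , drop = FALSE]
}

reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}
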