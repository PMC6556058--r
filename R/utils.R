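`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar numeric check used throughout input validation
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_ahc <- function(...) stop(sprintf(...), call. = FALSE)

# named lookup that fails loudly instead of returning NA
pget <- function(params, name) {
  if (!name %in% names(params)) {
    stop_ahc("parameter '%s' missing from parameter map", name)
  }
  unname(params[[name]])
}
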