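# Condition helpers: every user-facing failure carries a tissuespec_* class
# so callers (and the test suite) can distinguish format, value, metadata,
# consistency and configuration problems.

abort_format <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_format_error", ...)
}

abort_value <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_value_error", ...)
}

abort_metadata <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_metadata_error", ...)
}

abort_consistency <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_consistency_error", ...)
}

abort_config <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_config_error", ...)
}

abort_key <- function(message, ...) {
  rlang::abort(message, class = "tissuespec_key_error", ...)
}

# Row-wise max/min over the columns of a numeric matrix or data frame.
row_max <- function(m) {
  do.call(pmax, as.data.frame(m))
}

row_min <- function(m) {
  do.call(pmin, as.data.frame(m))
}

# sample() with the surprising scalar behaviour removed.
resample <- function(x, size, replace = TRUE) {
  x[sample.int(length(x), size, replace = replace)]
}
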