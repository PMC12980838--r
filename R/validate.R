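# Internal argument checks. All user-facing errors name the offending field.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < lower || (!allow_zero && x == lower)) {
    cmp <- if (allow_zero) ">=" else ">"
    stop_field(field, sprintf("must be %s %g", cmp, lower))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_field(field, "must be TRUE or FALSE")
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed) || seed != round(seed)) {
    stop_field("seed", "must be a single integer; seeds are mandatory")
  }
  as.integer(seed)
}
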