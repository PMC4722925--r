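# Internal helpers: condition classes, argument checks, unit conversion.

MINUTES_PER_HOUR <- 60

lq_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lqfrac_error")))
}

lq_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "lqfrac_warning")))
}

# Validation error naming the offending field.
check_positive_scalar <- function(x, field, zero_ok = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (zero_ok) x >= 0 else x > 0)
  if (!ok) {
    lq_abort(
      sprintf(
        "`%s` must be a single finite %s number, got %s",
        field, if (zero_ok) "non-negative" else "strictly positive",
        deparse(substitute(x, parent.frame()))[1]
      ),
      "lqfrac_validation_error"
    )
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    abs(x - round(x)) < 1e-8 && x >= min
  if (!ok) {
    lq_abort(
      sprintf("`%s` must be a single integer >= %d", field, min),
      "lqfrac_validation_error"
    )
  }
  as.integer(round(x))
}

min_to_h <- function(x) x / MINUTES_PER_HOUR

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with a NULL seed the expression just uses the current RNG stream.
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}
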