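# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial rounding used when reporting amounts in whole crowns or oere:
#' ties round away from zero rather than to even (base [round()] uses
#' banker's rounding, which is unsuitable for audited monetary tables).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_int <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x))
    abort("`%s` must be a single integer", name)
  if (positive && x <= 0) abort("`%s` must be positive", name)
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    abort("`%s` must lie in [0, 1]", name)
  x
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) abort("`%s` must be >= 0", name)
  x
}

# year index (1 or 2) from day since randomisation; days 0-364 year 1,
# 365-729 year 2 (events assigned by start day, episodes not split)
study_year <- function(day, year_days = 365L) {
  ifelse(day < year_days, 1L, 2L)
}

# deterministic child seed (keeps derived seeds below 2^31); double
# arithmetic to avoid integer overflow for large parent seeds
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483587)
}
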