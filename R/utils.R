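# Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g", name, lower)
  if (x > upper) stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min)
    stopf("`%s` must be an integer >= %d", name, min)
  as.integer(x)
}

assert_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed))
    stopf("`seed` must be a single integer")
  as.integer(seed)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Positive draw: normal truncated at zero by resampling-free clipping at a
# small floor, adequate for speeds/amplitudes that must stay non-negative.
rnorm_pos <- function(n, mean, sd, floor = 0) {
  pmax(rnorm(n, mean, sd), floor)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
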