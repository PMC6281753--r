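# Internal helpers shared across the package.

# round() in R rounds half to even; the printed report tables use
# conventional half-up rounding, so we do it explicitly.
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_fmt <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic sample ordering used everywhere: lexicographic by ID, fixed
# C collation so the order does not depend on the session locale.
order_ids <- function(ids) order(as.character(ids), method = "radix")

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_fmt("'%s' must be a single number in [%s, %s]", name,
             format(lo), format(hi))
  }
  invisible(x)
}
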