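# internal helpers shared across modules

# derive a reproducible child seed from a base seed and an index; kept
# strictly below 2^31 so it is always a valid R integer seed
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483647)
}

# run code under a seed without disturbing the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside its admissible range", name, x),
         call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_number(x, name, lower = lower)
  if (x != as.integer(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(as.integer(x))
}

# round to the integer NRS grid and clamp to [0, 10]
clamp_nrs <- function(x) pmin(10L, pmax(0L, as.integer(round(x))))
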