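# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a fixed offset.
# Kept strictly below 2^31 - 1 so set.seed() always accepts it.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 131L + offset * 7919) %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

# Integer state codes from a factor-like column; levels give the alphabet.
state_codes <- function(x) {
  if (is.factor(x)) as.integer(x) else as.integer(x)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
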