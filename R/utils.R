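# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream; a NULL seed uses the current stream as-is.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    code
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Derived seeds for sub-computations; drawn with replacement so that a
# prefix of a longer draw equals a shorter draw under the same seed.
draw_seeds <- function(k) {
  sample.int(2147483647L, k, replace = TRUE)
}

# Round half away from zero (matching how integer I2 percentages are
# displayed); base round() rounds half to even.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sctbias_domain_error")
}

stop_validation <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sctbias_validation_error")
}

stop_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "sctbias_schema_error")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == as.integer(x)
}
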