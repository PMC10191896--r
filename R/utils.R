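# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All randomness in the package funnels through this.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# Derive a reproducible per-stage / per-unit seed from a master seed.
# Keeps results stable when unrelated stages change their RNG consumption,
# and keeps patient i's draws independent of how many patients follow
# (counter-based stream). Result always fits in a 32-bit signed integer.
derive_seed <- function(seed, label, counter = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 69621 + as.numeric(counter) * 16807) %% 2147483647)
}

# Round to the step grid, guarding against floating-point drift
# (0.03 / 0.01 style arithmetic).
snap <- function(x, digits = 9) round(x, digits)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
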