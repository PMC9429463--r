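# Internal numeric helpers shared across modules.

# Round half away from zero (base round() is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clip to the 8-bit digital-number range.
clip_dn <- function(x) pmin(pmax(x, 0), 255)

# Counter-based seed derivation: every stream of randomness in the package
# is keyed off a single user seed through this map, so batches, scenes and
# illumination draws are reproducible without shared global state.
# Result always lies in [0, 2^31 - 2].
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 9973) %% 2147483629)
}

# Extract one channel as a height x width matrix; plain x[, , i] drops
# dimensions for 1-pixel-wide or 1-pixel-tall images.
channel <- function(x, i) {
  m <- x[, , i, drop = FALSE]
  dim(m) <- dim(x)[1:2]
  m
}
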