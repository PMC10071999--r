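# Internal helpers shared across modules.

# Run `fn` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, fn) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("invalid argument: `seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  fn()
}

# Derive a reproducible sub-seed from a master seed and a stream index,
# kept within the 32-bit signed range. Subsetting a dataset must not
# reshuffle per-image noise, so streams are keyed by absolute index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647)
}

# Round to nearest integer, ties away from zero (base round() is banker's).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_invalid <- function(...) {
  stop("invalid argument: ", sprintf(...), call. = FALSE)
}
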