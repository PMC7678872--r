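# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulation calls do not perturb the session stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# floor(x / y) robust to binary floating-point representation of durations
# like 0.09 s (180 / 0.09 must give 2000 frames, not 1999).
floor_div <- function(x, y) as.integer(floor(x / y + 1e-9))

# Derive a stream of distinct 31-bit sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_if_not_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}
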