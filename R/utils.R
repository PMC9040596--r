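# Internal helpers: argument checking and seed plumbing.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 strict_min = FALSE) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x),
              paste0("`", name, "` must be a single finite number."))
  if (strict_min) {
    assert_that(x > min, paste0("`", name, "` must be > ", min, "."))
  } else {
    assert_that(x >= min, paste0("`", name, "` must be >= ", min, "."))
  }
  assert_that(x <= max, paste0("`", name, "` must be <= ", max, "."))
  invisible(x)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; if `seed` is
# NULL the global RNG stream is used (and advanced) as-is.
with_seed_or_global <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    assert_scalar_number(seed, "seed")
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive `n` child seeds from one root seed, each a valid 32-bit integer.
# Deterministic: the same root always yields the same children.
derive_seeds <- function(seed, n) {
  assert_scalar_number(n, "n", min = 1)
  with_seed_or_global(seed, sample.int(.Machine$integer.max, n))
}
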