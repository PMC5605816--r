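# Internal helpers: scoped RNG and deterministic seed derivation.

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Mix a base seed with stream indices into a new seed in [1, 2^31 - 2].
# Simple multiplicative hash; collisions across distinct index tuples are
# astronomically unlikely at the scales used here.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed %% m)
  for (k in idx) {
    s <- (s * 48271 + as.double(k) * 16807 + 12345) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

stopifnot_scalar_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%g, %g], got %s",
                 name, lo, hi, paste(format(x), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
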