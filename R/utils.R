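# Internal helpers shared across the package.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && abs(x - round(x)) < 1e-8

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this helper so that one global
# seed expands into reproducible per-component sub-streams.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Linear interpolation across flagged samples; endpoints take the nearest
# valid value. `bad` is a logical mask; at least one sample must be valid.
interp_over <- function(x, bad) {
  if (!any(bad)) return(x)
  good <- which(!bad)
  stats::approx(good, x[good], xout = seq_along(x), rule = 2)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
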