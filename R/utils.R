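# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed (kept inside 32 bits).
.childSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7919L
}

.assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive number")
  invisible(x)
}

# Population (divide-by-N) standard deviation.
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

# Fixed 9-significant-digit numeric formatting used for serialized results,
# so determinism checks can be byte-level.
.fmtNum <- function(x) signif(x, 9)
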