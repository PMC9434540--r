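# Internal helpers: deterministic seeding and argument checks.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Mix a root seed with stream identifiers into a new 31-bit seed.
# Plain LCG-style mixing; every source of randomness in the package draws
# its seed through this so that any sub-computation is reproducible in
# isolation from (root seed, stream ids).
mix_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ids) {
    s <- (s * 1103515245 + as.double(k) * 12345 + 12345) %% 2147483647
  }
  as.integer(s)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
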