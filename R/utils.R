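# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed fan-out from a single global seed.
# Stage seeds must stay below 2^31 (R integers are 32-bit).
stageSeed <- function(seed, stage) {
  stages <- c("simulate", "cna", "de", "network", "impact", "transfer",
              "permute", "baseline", "holdout")
  k <- match(stage, stages)
  if (is.na(k)) stop("unknown pipeline stage: ", stage)
  as.integer((as.numeric(seed) * 97L + k * 1009L) %% 2147483647)
}

assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop("'", name, "' must be a single integer >= ", min)
  as.integer(x)
}

assertFraction <- function(x, name, lo = 0, hi = 1, open_lo = FALSE,
                           open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single number")
  if (x < lo || x > hi || (open_lo && x == lo) || (open_hi && x == hi))
    stop("'", name, "' outside ", if (open_lo) "(" else "[", lo, ", ", hi,
         if (open_hi) ")" else "]")
  as.numeric(x)
}

spectralRadius <- function(W) {
  if (nrow(W) == 0L) return(0)
  max(Mod(eigen(W, only.values = TRUE)$values))
}
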