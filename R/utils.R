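## internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. `seed = NULL` is a no-op.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}

# smallest power of two >= n, computed by doubling (no log2 rounding risk)
nextPow2 <- function(n) {
  stopifnot(n >= 1)
  p <- 1
  while (p < n) p <- 2 * p
  p
}

# half-open band membership [lo, hi) on a frequency grid
bandMask <- function(freqs, band) {
  freqs >= band[1] & freqs < band[2]
}

# unscaled median absolute deviation (no 1.4826 consistency factor)
madRaw <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

# format doubles so that as.numeric() round-trips bit-exactly
fmtNum <- function(x) {
  sprintf("%.17g", x)
}
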