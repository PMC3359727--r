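# Internal numeric helpers shared by the curve-fitting modules.

# Centered moving average; window must be odd.  Edge points use the
# truncated window so the output has the same length as the input.
movingAverage <- function(x, window = 3L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  n <- length(x)
  half <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Indices of strict-or-plateau local maxima of a numeric vector.
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  for (i in 2L:(n - 1L)) {
    if (x[i] >= x[i - 1L] && x[i] > x[i + 1L]) idx <- c(idx, i)
  }
  idx
}

# Run a block with a locally seeded RNG, restoring the caller's RNG state.
# Used for the bounded-restart jitter in the iterative fitters so that fits
# are reproducible without clobbering the user's random stream.
withLocalSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Format a number with enough significant digits for lossless round trips
# through text (the XML interchange guarantees >= 9 significant digits).
fmtNum <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
}

isFlagTrue <- function(x) isTRUE(as.logical(x))

# argmax with "latest index" tie-break (used by curve truncation).
argmaxLast <- function(x) {
  m <- max(x)
  max(which(x == m))
}
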