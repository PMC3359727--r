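# Shared fixture builders and small independent oracles.

# Independent brute-force scan over all runs (oracle for
# longestDisorderStretch).
bruteLongestRun <- function(calls) {
  best <- 0L
  for (start in seq_along(calls)) {
    for (end in start:length(calls)) {
      if (all(calls[start:end])) best <- max(best, end - start + 1L)
    }
  }
  best
}

# Independent exhaustive search for the best single split of (x, y):
# every midpoint between adjacent observed values, SSE computed directly.
bruteBestSplit <- function(x, y, minLeaf = 1L) {
  vals <- sort(unique(x[!is.na(x)]))
  if (length(vals) < 2L) return(NULL)
  mids <- (vals[-1] + vals[-length(vals)]) / 2
  sse <- function(v) sum((v - mean(v))^2)
  best <- NULL
  for (m in mids) {
    l <- which(x <= m)
    r <- which(x > m)
    if (length(l) < minLeaf || length(r) < minLeaf) next
    g <- sse(y) - sse(y[l]) - sse(y[r])
    if (is.null(best) || g > best$gain + 1e-12)
      best <- list(threshold = m, gain = g)
  }
  best
}

# Independent leaf routing (oracle for leaf-mean exactness): returns the
# leaf mean for a complete (no-NA) feature row by walking the node list.
routeOracle <- function(node, v) {
  while (!isTRUE(node$leaf)) {
    node <- if (v[node$feature] <= node$threshold) node$left else node$right
  }
  node$mean
}

# A deterministic two-transition DSF curve builder (no files involved).
makeDsfCurve <- function(baseline = 200, tm = 323, s = 1.5, delta_f = 1000,
                         noise = 0, seed = 1, tmin = 293.15, tmax = 363.15,
                         step = 0.5) {
  temp <- seq(tmin, tmax, by = step)
  f <- rep(baseline, length(temp))
  for (j in seq_along(tm))
    f <- f + delta_f[j] / (1 + exp((tm[j] - temp) / s[j]))
  if (noise > 0) {
    set.seed(seed)
    f <- f * (1 + rnorm(length(f), 0, noise))
  }
  dsfCurve(temp, f, "A1")
}

# Deterministic Gaussian-mixture chromatogram in fraction coordinates.
makeSecChrom <- function(height = 100, center = 20, width = 2, noise = 0,
                         seed = 1, fracMax = 40, pointsPerFraction = 10) {
  x <- seq(1, fracMax, length.out = fracMax * pointsPerFraction)
  a <- numeric(length(x))
  for (i in seq_along(height))
    a <- a + height[i] * exp(-(x - center[i])^2 / (2 * width[i]^2))
  if (noise > 0) {
    set.seed(seed)
    a <- a + rnorm(length(a), 0, noise * max(height))
  }
  secChromatogram(x, a)
}

makePeaks <- function(rh, intensity_pct, pd_pct = rep(10, length(rh))) {
  data.frame(rh = rh, pd = rh * pd_pct / 100, pd_pct = pd_pct,
             intensity_pct = intensity_pct,
             mass_pct = rep(100 / length(rh), length(rh)))
}

# Cohort where the score is fully determined by one feature threshold.
makePlantedCohort <- function(n = 60, feature = "l_dis", threshold = 40,
                              low = 5, high = 0, sigma = 0, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    r_dsf = rbeta(n, 2, 5), yield = sample(0:5, n, replace = TRUE),
    r_sec = rbeta(n, 1.5, 8), p_maj = rbeta(n, 6, 2),
    mw_mono = rlnorm(n, log(40000), 0.5), l_dis = rgeom(n, 1 / 30))
  raw <- ifelse(df[[feature]] <= threshold, low, high)
  df$score <- pmin(pmax(round(raw + rnorm(n, 0, sigma)), 0), 6)
  df
}
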