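# Size-exclusion chromatography: ASCII parsing, time/volume -> fraction
# conversion, Gaussian mixture fitting, pooled purity and the
# single-Gaussian residual statistic r_sec = RSS1/TSS.

#' Construct a SEC chromatogram
#'
#' @param fraction continuous fraction coordinates (see
#'   [SecChromatogram-class]).
#' @param absorbance mAU.
#' @param flowRate mL/min. @param fractionSize mL. @param collectionStart min.
#' @return a [SecChromatogram-class].
#' @export
secChromatogram <- function(fraction, absorbance, flowRate = 1,
                            fractionSize = 1, collectionStart = 0) {
  new("SecChromatogram", fraction = as.numeric(fraction),
      absorbance = as.numeric(absorbance), flowRate = flowRate,
      fractionSize = fractionSize, collectionStart = collectionStart)
}

parseDocKeys <- function(lines) {
  grab <- function(pattern, key) {
    hit <- grep(pattern, lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L)
      stop(sprintf("run-log metadata key missing: %s", key))
    num <- regmatches(hit[1], regexpr("[-+0-9.eE]+\\s*$", hit[1]))
    val <- suppressWarnings(as.numeric(trimws(num)))
    if (length(val) == 0L || is.na(val))
      stop(sprintf("run-log metadata key unreadable: %s", key))
    val
  }
  list(flowRate = grab("flow\\s*rate", "flow rate"),
       fractionSize = grab("fraction\\s*size", "fraction size"),
       collectionStart = grab("collection\\s*start", "collection start"))
}

#' Parse a SEC absorbance trace plus run log
#'
#' The curve file holds (time, absorbance) pairs in minutes and mAU, any
#' non-numeric header lines skipped; the doc file supplies `Flow rate`,
#' `Fraction size` and `Collection start` lines (`key: value`, units
#' mL/min, mL, min).  The time axis is converted to continuous fraction
#' coordinates `1 + (t - start) * flow / size`; the integer fraction of a
#' point is its floor on half-open volume intervals (see [fractionIndex()]),
#' with pre-collection points assigned fraction 0.
#'
#' @param curvePath curve.asc-style file. @param docPath doc.asc-style file.
#' @return a [SecChromatogram-class].
#' @export
readSecAscii <- function(curvePath, docPath) {
  doc <- parseDocKeys(readLines(docPath, warn = FALSE))
  lines <- readLines(curvePath, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- lapply(lines, function(l) {
    suppressWarnings(as.numeric(strsplit(trimws(l), "[,;\t ]+")[[1]]))
  })
  keep <- vapply(vals, function(v) length(v) >= 2 && !anyNA(v[1:2]), logical(1))
  vals <- vals[keep]
  if (length(vals) < 10L) stop("SEC curve file has fewer than 10 data points")
  t <- vapply(vals, `[`, numeric(1), 1L)
  a <- vapply(vals, `[`, numeric(1), 2L)
  frac <- 1 + (t - doc$collectionStart) * doc$flowRate / doc$fractionSize
  secChromatogram(frac, a, doc$flowRate, doc$fractionSize,
                  doc$collectionStart)
}

#' Integer fraction index of points on a chromatogram
#'
#' Fractions are 1-based on half-open volume intervals; coordinates before
#' the start of collection map to fraction 0.
#'
#' @param chrom a [SecChromatogram-class] (or numeric fraction coordinates).
#' @return integer vector of fraction numbers.
#' @export
fractionIndex <- function(chrom) {
  f <- if (is(chrom, "SecChromatogram")) chrom@fraction else chrom
  ifelse(f >= 1, floor(f), 0)
}

#' Initial peak estimates for Gaussian fitting
#'
#' Local maxima of the 5-point-smoothed trace lying above a noise floor of
#' `floorMad` raw median absolute deviations above the median, returned in
#' descending height order.
#'
#' @param chrom a [SecChromatogram-class].
#' @param floorMad noise-floor multiplier.
#' @return data.frame with columns `height` and `center` (possibly 0 rows).
#' @export
initialPeakEstimates <- function(chrom, floorMad = 3) {
  stopifnot(length(chrom@absorbance) >= 10L)
  a <- chrom@absorbance
  sm <- movingAverage(a, 5L)
  floorLevel <- median(a) + floorMad * mad(a)
  idx <- localMaxima(sm)
  idx <- idx[sm[idx] > floorLevel]
  idx <- idx[order(sm[idx], decreasing = TRUE)]
  data.frame(height = sm[idx], center = chrom@fraction[idx])
}

gaussMixEval <- function(x, h, c, w) {
  y <- numeric(length(x))
  for (i in seq_along(h))
    y <- y + h[i] * exp(-(x - c[i])^2 / (2 * w[i]^2))
  y
}

#' Fit a Gaussian mixture to a chromatogram
#'
#' Least-squares fit of `A(f) = sum_i h_i exp(-(f - c_i)^2 / (2 w_i^2))` by
#' Levenberg--Marquardt with restarts, seeded from [initialPeakEstimates()].
#' Components are returned sorted by center.
#'
#' @param chrom a [SecChromatogram-class].
#' @param k number of components; default, the number of initial peak
#'   estimates (at least 1).
#' @return a [SecFit-class] (pool/purity/rSec unset; see [analyzeSec()]).
#' @export
fitGaussians <- function(chrom, k = NULL) {
  x <- chrom@fraction
  a <- chrom@absorbance
  est <- initialPeakEstimates(chrom)
  if (is.null(k)) k <- max(1L, nrow(est))
  if (length(x) < 3L * k + 2L)
    stop(sprintf("too few points (%d) for k = %d Gaussian components",
                 length(x), k))
  h0 <- est$height
  c0 <- est$center
  if (length(h0) < k) {
    need <- k - length(h0)
    spread <- seq(min(x), max(x), length.out = need + 2L)[-c(1, need + 2L)]
    h0 <- c(h0, rep(max(a) / 2, need))
    c0 <- c(c0, spread)
  }
  h0 <- h0[seq_len(k)]; c0 <- c0[seq_len(k)]
  totalMass <- sum(a)
  w0 <- if (totalMass > 0)
    max(sqrt(sum(a * (x - sum(a * x) / totalMass)^2) / totalMass) / k, 0.5)
  else 1

  resid <- function(p) {
    m <- matrix(p, nrow = 3)
    a - gaussMixEval(x, m[1, ], m[2, ], m[3, ])
  }
  lower <- rep(c(0, min(x) - diff(range(x)), 1e-4), k)
  upper <- rep(c(Inf, max(x) + diff(range(x)), diff(range(x))), k)
  best <- NULL
  withLocalSeed(4823L + k, {
    for (attempt in 1:5) {
      c1 <- c0; w1 <- rep(w0, k)
      if (attempt > 1) {
        c1 <- c1 + rnorm(k, 0, w0)
        w1 <- w1 * runif(k, 0.5, 2)
      }
      p0 <- as.vector(rbind(h0, c1, w1))
      ans <- tryCatch(
        nls.lm(par = p0, fn = resid, lower = lower, upper = upper,
               control = nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(ans)) next
      ok <- ans$info %in% 1:4
      rss <- sum(ans$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(par = ans$par, rss = rss, ok = ok)
      if (ok && rss <= 1e-12 * sum(a^2)) break
    }
  })
  if (is.null(best) || !best$ok)
    stop(sprintf("Gaussian fit did not converge%s",
                 if (is.null(best)) "" else sprintf(" (best RSS %g)", best$rss)))
  m <- matrix(best$par, nrow = 3)
  ord <- order(m[2, ])
  comp <- data.frame(height = m[1, ord], center = m[2, ord], width = m[3, ord])
  new("SecFit", components = comp, poolRange = c(NA_real_, NA_real_),
      purityPool = NA_real_, rSec = NA_real_, rss = best$rss)
}

# Analytic integral of one component over [a, b].
gaussIntegral <- function(h, c, w, a, b) {
  h * w * sqrt(2 * pi) * (pnorm((b - c) / w) - pnorm((a - c) / w))
}

#' Percent purity of the pooled fractions
#'
#' The pool `[first, last]` (inclusive fraction indices) is integrated as the
#' continuous fraction interval `[first, last + 1)`.  Purity is 100 x the
#' integral of the pool's main component (the component with the largest
#' integral inside the pool) over the integral of the full mixture.
#'
#' @param fit a [SecFit-class].
#' @param poolRange integer vector `c(first, last)`.
#' @return percent in `[0, 100]`, or `NA` if the mixture has no mass in the
#'   pool.
#' @export
poolPurity <- function(fit, poolRange) {
  stopifnot(length(poolRange) == 2L, poolRange[2] >= poolRange[1])
  a <- poolRange[1]
  b <- poolRange[2] + 1
  comp <- fit@components
  ints <- mapply(gaussIntegral, comp$height, comp$center, comp$width,
                 MoreArgs = list(a = a, b = b))
  total <- sum(ints)
  if (!is.finite(total) || total <= .Machine$double.eps) return(NA_real_)
  100 * max(ints) / total
}

#' Single-Gaussian residual statistic
#'
#' `r_sec = RSS1 / TSS`, where RSS1 is the residual sum of squares of the
#' best single-Gaussian fit and TSS the total sum of squares about the mean
#' absorbance; clamped to `[0, 1]`.  Near 0 for a clean monodisperse peak,
#' large for multi-peak or misshapen profiles.  Always computed from its own
#' one-component fit, independent of any mixture order chosen for display.
#'
#' @param chrom a [SecChromatogram-class].
#' @return dimensionless value in `[0, 1]`, or `NA` for a constant trace.
#' @export
singleGaussianResidual <- function(chrom) {
  a <- chrom@absorbance
  tss <- sum((a - mean(a))^2)
  if (tss <= .Machine$double.eps) return(NA_real_)
  fit1 <- fitGaussians(chrom, k = 1L)
  min(max(fit1@rss / tss, 0), 1)
}

#' Full SEC analysis
#'
#' Convenience wrapper: mixture fit ([fitGaussians()]), single-Gaussian
#' residual ([singleGaussianResidual()]) and, when a pool range is given,
#' pooled purity ([poolPurity()]).
#'
#' @param chrom a [SecChromatogram-class].
#' @param k mixture order (default from [initialPeakEstimates()]).
#' @param pool optional `c(first, last)` pooled fraction range.
#' @return a completed [SecFit-class].
#' @export
analyzeSec <- function(chrom, k = NULL, pool = NULL) {
  fit <- fitGaussians(chrom, k)
  fit@rSec <- singleGaussianResidual(chrom)
  if (!is.null(pool)) {
    fit@poolRange <- as.numeric(pool)
    fit@purityPool <- poolPurity(fit, pool)
  }
  validObject(fit)
  fit
}

#' @describeIn analyzeSec fitted component table (height, center, width).
#' @param x a [SecFit-class].
#' @export
setMethod("components", "SecFit", function(x) x@components)

#' @describeIn analyzeSec the single-Gaussian residual fraction.
#' @export
setMethod("rSec", "SecFit", function(x) x@rSec)

#' @describeIn analyzeSec percent purity of the pooled fractions.
#' @export
setMethod("purityPool", "SecFit", function(x) x@purityPool)

setMethod("show", "SecFit", function(object) {
  cat(sprintf("SecFit: %d component%s, RSS %.4g\n",
              nrow(object@components),
              if (nrow(object@components) == 1) "" else "s", object@rss))
  comp <- object@components
  for (i in seq_len(nrow(comp)))
    cat(sprintf("   h %.4g mAU  center %.3f  width %.3f\n",
                comp$height[i], comp$center[i], comp$width[i]))
  if (!is.na(object@purityPool))
    cat(sprintf("  pool %g..%g purity %.2f%%\n", object@poolRange[1],
                object@poolRange[2], object@purityPool))
  if (!is.na(object@rSec))
    cat(sprintf("  single-Gaussian residual r_sec %.4g\n", object@rSec))
})
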