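# Differential scanning fluorimetry: parsing, curve truncation, Boltzmann
# transition fitting and the predictor ratio r_dsf.
#
# Model: F(T) = baseline + sum_j dF_j / (1 + exp((Tm_j - T) / s_j))
# Derived per transition: max dF/dT = dF/(4 s) at Tm, and the full width at
# half maximum of dF/dT, FWHM = 2 ln(3 + 2 sqrt(2)) s.

FWHM_FACTOR <- 2 * log(3 + 2 * sqrt(2))   # ~3.5255

#' Construct a DSF curve
#'
#' @param temperature numeric, Kelvin or Celsius (values below 150 are taken
#'   to be Celsius and converted to Kelvin).
#' @param fluorescence numeric, arbitrary units.
#' @param wellLabel well identifier.
#' @return a [DsfCurve-class].
#' @export
dsfCurve <- function(temperature, fluorescence, wellLabel = "A1") {
  if (max(temperature) < 150) temperature <- temperature + 273.15
  new("DsfCurve", wellLabel = wellLabel,
      temperature = as.numeric(temperature),
      fluorescence = as.numeric(fluorescence))
}

#' Parse a DSF melt-curve export
#'
#' Reads plate-reader text exports with temperature in the first column and
#' one fluorescence column per well, delimited by commas, semicolons, tabs or
#' spaces (dialect auto-detected).  Well labels come from a header row when
#' present, else positionally as A1..H12.  Celsius temperatures are converted
#' to Kelvin.
#'
#' @param path text file.
#' @return list of [DsfCurve-class], one per intensity column.
#' @export
readDsfCsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("DSF file too short")
  tok <- lapply(lines, function(l) {
    strsplit(trimws(l), "[,;\t ]+")[[1]]
  })
  first <- suppressWarnings(as.numeric(tok[[1]]))
  hasHeader <- any(is.na(first))
  labels <- NULL
  if (hasHeader) {
    labels <- tok[[1]][-1]
    tok <- tok[-1]
  }
  ncols <- length(tok[[1]])
  if (ncols < 2L) stop("need a temperature column plus >= 1 intensity column")
  for (i in seq_along(tok)) {
    if (length(tok[[i]]) != ncols)
      stop(sprintf("ragged row at line %d: expected %d fields, got %d",
                   i + as.integer(hasHeader), ncols, length(tok[[i]])))
  }
  mat <- vapply(tok, function(t) suppressWarnings(as.numeric(t)),
                numeric(ncols))
  mat <- t(mat)
  if (anyNA(mat)) stop("non-numeric data value in DSF file")
  temp <- mat[, 1]
  if (any(diff(temp) <= 0))
    stop("temperature column must be strictly increasing")
  nw <- ncols - 1L
  if (is.null(labels) || length(labels) != nw) labels <- plateLabels(nw)
  lapply(seq_len(nw), function(j)
    dsfCurve(temp, mat[, j + 1L], wellLabel = labels[j]))
}

plateLabels <- function(n) {
  lab <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
  if (n > length(lab)) lab <- c(lab, paste0("W", seq_len(n - length(lab))))
  lab[seq_len(n)]
}

#' Truncate a DSF curve to its fitting region
#'
#' Fitting stops at the intensity maximum after the highest-temperature
#' transition (dye fluorescence decays on aggregation past the melt).  The
#' region runs from the first point to the global maximum of the
#' 3-point-moving-average-smoothed fluorescence; ties break to the latest
#' index, so a monotone or flat curve keeps its full range.
#'
#' @param curve a [DsfCurve-class].
#' @return integer vector `c(first, last)` of the fit region.
#' @export
truncateCurve <- function(curve) {
  sm <- movingAverage(curve@fluorescence, 3L)
  c(1L, argmaxLast(sm))
}

boltzmannEval <- function(temp, baseline, tm, s, delta_f) {
  f <- rep(baseline, length(temp))
  for (j in seq_along(tm))
    f <- f + delta_f[j] / (1 + exp((tm[j] - temp) / s[j]))
  f
}

unpackPars <- function(p, k) {
  list(baseline = p[1],
       tm = p[1 + 3 * (seq_len(k) - 1) + 1],
       s = p[1 + 3 * (seq_len(k) - 1) + 2],
       delta_f = p[1 + 3 * (seq_len(k) - 1) + 3])
}

# Initial Tm guesses: the k largest peaks of the smoothed derivative.
dsfStartValues <- function(temp, fl, k) {
  sm <- movingAverage(fl, 5L)
  d <- diff(sm) / diff(temp)
  dsm <- movingAverage(d, 5L)
  tmid <- (temp[-1] + temp[-length(temp)]) / 2
  cand <- localMaxima(dsm)
  cand <- cand[order(dsm[cand], decreasing = TRUE)]
  tms <- tmid[cand]
  if (length(tms) < k) {
    extra <- seq(min(temp), max(temp),
                 length.out = k - length(tms) + 2L)[-c(1, k - length(tms) + 2L)]
    tms <- c(tms, extra)
  }
  tms <- sort(tms[seq_len(k)])
  list(baseline = min(fl), tm = tms, s = rep(2, k),
       delta_f = rep(max(diff(range(fl)), 1e-6) / k, k))
}

#' Fit Boltzmann transitions to a DSF curve
#'
#' Iterative Levenberg--Marquardt least squares of `k` Boltzmann transitions
#' plus a constant baseline over the truncated fit region (see
#' [truncateCurve()]).  Initial midpoints seed at the largest peaks of the
#' smoothed derivative; up to 5 restarts with jittered seeds are attempted
#' before giving up.  The steepest transition (largest `delta_f/(4 s)`) is
#' taken as the major one; override afterwards with `majorIndex<-`.
#'
#' @param curve a [DsfCurve-class].
#' @param k number of transitions (>= 1); use [selectTransitionCount()] to
#'   choose automatically.
#' @param keepCurve store the source curve in the returned object.
#' @return a [DsfFit-class].
#' @export
fitBoltzmann <- function(curve, k = 1L, keepCurve = TRUE) {
  stopifnot(is(curve, "DsfCurve"), k >= 1L)
  region <- truncateCurve(curve)
  idx <- region[1]:region[2]
  if (length(idx) < 4L * k + 2L)
    stop(sprintf("fit region too short (%d points) for k = %d transitions",
                 length(idx), k))
  temp <- curve@temperature[idx]
  fl <- curve@fluorescence[idx]

  resid <- function(p) fl - {
    u <- unpackPars(p, k)
    boltzmannEval(temp, u$baseline, u$tm, u$s, u$delta_f)
  }
  lower <- c(-Inf, rep(c(min(temp) - 50, 1e-3, -Inf), k))
  upper <- c(Inf, rep(c(max(temp) + 50, 50, Inf), k))
  init <- dsfStartValues(temp, fl, k)

  best <- NULL
  withLocalSeed(20120516L + k, {
    for (attempt in 1:5) {
      tm0 <- init$tm
      s0 <- init$s
      if (attempt > 1) {
        tm0 <- tm0 + rnorm(k, 0, 3)
        s0 <- s0 * runif(k, 0.5, 2)
      }
      p0 <- c(init$baseline,
              as.vector(rbind(tm0, s0, init$delta_f)))
      ans <- tryCatch(
        nls.lm(par = p0, fn = resid, lower = lower, upper = upper,
               control = nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(ans)) next
      ok <- ans$info %in% 1:4
      rss <- sum(ans$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(par = ans$par, rss = rss, ok = ok)
      if (ok && rss <= 1e-12 * sum(fl^2)) break
    }
  })
  if (is.null(best))
    stop("Boltzmann fit failed to converge")
  if (!best$ok)
    stop(sprintf("Boltzmann fit did not converge after restarts (best RSS %g)",
                 best$rss))

  u <- unpackPars(best$par, k)
  ord <- order(u$tm)
  tab <- data.frame(tm = u$tm[ord], s = u$s[ord], delta_f = u$delta_f[ord])
  tab$max_slope <- tab$delta_f / (4 * tab$s)
  tab$fwhm <- FWHM_FACTOR * tab$s
  major <- which.max(tab$max_slope)
  f30 <- boltzmannEval(303.15, u$baseline, tab$tm, tab$s, tab$delta_f)
  fTm <- boltzmannEval(tab$tm[major], u$baseline, tab$tm, tab$s, tab$delta_f)
  new("DsfFit", baseline = u$baseline, transitions = tab,
      majorIndex = as.integer(major), f30 = f30, fTm = fTm,
      rDsf = f30 / fTm, fitRegion = as.integer(region), rss = best$rss,
      curve = if (keepCurve) curve else NULL, converged = TRUE)
}

#' Choose the number of Boltzmann transitions
#'
#' Fits 1..`kMax` transitions and returns the smallest `k` whose BIC is not
#' improved by more than `bicThreshold` at `k + 1`.  A warning is emitted
#' when even the single-transition fit explains almost none of the variance
#' (no clear transition in the data).
#'
#' @param curve a [DsfCurve-class].
#' @param kMax largest transition count considered.
#' @param bicThreshold required BIC improvement to accept a further
#'   transition.
#' @return integer transition count.
#' @export
selectTransitionCount <- function(curve, kMax = 3L, bicThreshold = 10) {
  stopifnot(kMax >= 1L)
  region <- truncateCurve(curve)
  idx <- region[1]:region[2]
  fl <- curve@fluorescence[idx]
  n <- length(fl)
  bic <- function(fit, k) n * log(fit@rss / n) + (3 * k + 1) * log(n)
  fit1 <- fitBoltzmann(curve, 1L, keepCurve = FALSE)
  tss <- sum((fl - mean(fl))^2)
  if (fit1@rss > 0.95 * tss)
    warning("no clear melt transition: fit barely improves on a flat baseline")
  k <- 1L
  cur <- bic(fit1, 1L)
  while (k < kMax) {
    nxt <- tryCatch(fitBoltzmann(curve, k + 1L, keepCurve = FALSE),
                    error = function(e) NULL)
    if (is.null(nxt)) break
    b <- bic(nxt, k + 1L)
    if (b < cur - bicThreshold) {
      k <- k + 1L
      cur <- b
    } else break
  }
  k
}

#' Evaluate a fitted DSF model
#'
#' @param fit a [DsfFit-class].
#' @param temperature Kelvin.
#' @return fitted fluorescence.
#' @export
dsfModel <- function(fit, temperature) {
  boltzmannEval(temperature, fit@baseline, fit@transitions$tm,
                fit@transitions$s, fit@transitions$delta_f)
}

#' @describeIn fitBoltzmann per-transition parameter table.
#' @param x a [DsfFit-class].
#' @export
setMethod("transitions", "DsfFit", function(x) x@transitions)

#' @describeIn fitBoltzmann the predictor ratio F(303.15 K)/F(Tm_major).
#' @export
setMethod("rDsf", "DsfFit", function(x) x@rDsf)

#' @describeIn fitBoltzmann index of the major transition.
#' @export
setMethod("majorIndex", "DsfFit", function(x) x@majorIndex)

#' @describeIn fitBoltzmann override the major transition; `fTm` and `rDsf`
#'   are recomputed.
#' @param value new major index.
#' @export
setReplaceMethod("majorIndex", "DsfFit", function(x, value) {
  value <- as.integer(value)
  if (value < 1L || value > nrow(x@transitions))
    stop("major transition index out of range")
  x@majorIndex <- value
  x@fTm <- dsfModel(x, x@transitions$tm[value])
  x@rDsf <- x@f30 / x@fTm
  validObject(x)
  x
})

setMethod("show", "DsfFit", function(object) {
  k <- nrow(object@transitions)
  cat(sprintf("DsfFit: %d transition%s, baseline %.4g, RSS %.4g\n",
              k, if (k == 1) "" else "s", object@baseline, object@rss))
  tab <- object@transitions
  for (j in seq_len(k))
    cat(sprintf("  %s Tm %.2f K  s %.3f K  dF %.4g  max dF/dT %.4g  FWHM %.3f K\n",
                if (j == object@majorIndex) "*" else " ",
                tab$tm[j], tab$s[j], tab$delta_f[j], tab$max_slope[j],
                tab$fwhm[j]))
  cat(sprintf("  F(303.15 K) %.4g  F(Tm) %.4g  r_dsf %.4g\n",
              object@f30, object@fTm, object@rDsf))
})
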