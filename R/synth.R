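# Synthetic raw-data generators.  Every supported instrument dialect can be
# emulated offline, with the generative ground truth written alongside each
# fixture (JSON) so tests never re-derive it.

writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic DSF melt-curve CSV
#'
#' Writes an Opticon-style CSV (`Temperature` in Celsius plus one
#' fluorescence column per well) of a Boltzmann melt model with
#' multiplicative Gaussian noise, and optionally a post-transition linear
#' decay starting at `lastTm + 3 s` (dye release on aggregation), plus a
#' `*_truth.json` ground-truth record.
#'
#' @param dir output directory.
#' @param seed RNG seed.
#' @param baseline baseline fluorescence.
#' @param transitions data.frame/list with `tm` (K), `s` (K), `delta_f`.
#' @param noise multiplicative Gaussian noise fraction (0.01 = 1\%).
#' @param decaySlope fluorescence units per K lost after the decay onset
#'   (`NULL` for no decay).
#' @param tRange temperature range, K. @param step sampling step, K.
#' @param well well label.
#' @param name file stem.
#' @return invisibly, list with `csv`, `truth` paths and the truth record.
#' @export
synthDsfCurve <- function(dir, seed = 1L, baseline = 200,
                          transitions = data.frame(tm = 323, s = 1.5,
                                                   delta_f = 1000),
                          noise = 0.01, decaySlope = NULL,
                          tRange = c(293.15, 363.15), step = 0.5,
                          well = "A1", name = "dsf_synth") {
  transitions <- as.data.frame(transitions)
  temp <- seq(tRange[1], tRange[2], by = step)
  f <- boltzmannEval(temp, baseline, transitions$tm, transitions$s,
                     transitions$delta_f)
  onset <- NA_real_
  if (!is.null(decaySlope)) {
    onset <- max(transitions$tm + 3 * transitions$s)
    past <- temp > onset
    f[past] <- f[past] - decaySlope * (temp[past] - onset)
  }
  withLocalSeed(seed, {
    f <- f * (1 + rnorm(length(f), 0, noise))
  })
  csv <- file.path(dir, paste0(name, ".csv"))
  writeLines(c(paste("Temperature", well, sep = ","),
               paste(fmtNum(temp - 273.15), fmtNum(f), sep = ",")), csv)
  truth <- list(kind = "dsf", seed = seed, baseline = baseline,
                transitions = transitions, noise = noise,
                decay_onset = onset,
                f30 = boltzmannEval(303.15, baseline, transitions$tm,
                                    transitions$s, transitions$delta_f))
  tpath <- file.path(dir, paste0(name, "_truth.json"))
  writeTruth(truth, tpath)
  invisible(list(csv = csv, truth = tpath, record = truth))
}

#' Generate a synthetic SEC chromatogram (curve + run log)
#'
#' Writes an AKTA-style pair: `<name>_curve.asc` with (time, mAU) rows and
#' `<name>_doc.asc` with the flow-rate / fraction-size / collection-start
#' metadata, plus the ground truth.  Components are specified in fraction
#' coordinates; additive Gaussian noise is scaled to the tallest peak.
#'
#' @param dir output directory. @param seed RNG seed.
#' @param components data.frame/list with `height` (mAU), `center`
#'   (fraction), `width` (fraction sigma).
#' @param noise additive noise as a fraction of the tallest peak.
#' @param flowRate mL/min. @param fractionSize mL. @param collectionStart min.
#' @param nFractions span of the time axis, fractions.
#' @param pointsPerFraction sampling density.
#' @param name file stem.
#' @return invisibly, list with `curve`, `doc`, `truth` paths and record.
#' @export
synthSecChromatogram <- function(dir, seed = 1L,
                                 components = data.frame(height = 100,
                                                         center = 20,
                                                         width = 2),
                                 noise = 0, flowRate = 1, fractionSize = 2,
                                 collectionStart = 10, nFractions = 40,
                                 pointsPerFraction = 10,
                                 name = "sec_synth") {
  components <- as.data.frame(components)
  frac <- seq(1, nFractions, length.out = nFractions * pointsPerFraction)
  t <- collectionStart + (frac - 1) * fractionSize / flowRate
  a <- gaussMixEval(frac, components$height, components$center,
                    components$width)
  withLocalSeed(seed, {
    a <- a + rnorm(length(a), 0, noise * max(components$height))
  })
  curve <- file.path(dir, paste0(name, "_curve.asc"))
  writeLines(c("min\tmAU", paste(fmtNum(t), fmtNum(a), sep = "\t")), curve)
  doc <- file.path(dir, paste0(name, "_doc.asc"))
  writeLines(c(sprintf("Flow rate (ml/min): %s", fmtNum(flowRate)),
               sprintf("Fraction size (ml): %s", fmtNum(fractionSize)),
               sprintf("Collection start (min): %s", fmtNum(collectionStart))),
             doc)
  truth <- list(kind = "sec", seed = seed, components = components,
                noise = noise, flow_rate = flowRate,
                fraction_size = fractionSize,
                collection_start = collectionStart)
  tpath <- file.path(dir, paste0(name, "_truth.json"))
  writeTruth(truth, tpath)
  invisible(list(curve = curve, doc = doc, truth = tpath, record = truth))
}

#' Generate a synthetic DLS peak-table export
#'
#' Writes a Dynamics-style tab-delimited peak table (and an optional
#' intensity-versus-radius histogram section), plus ground truth.  Mass
#' percentages default to intensity percentages re-weighted toward small
#' particles, as in real exports.
#'
#' @param dir output directory.
#' @param peaks data.frame/list with `rh` (nm), `pd_pct`, `intensity_pct`
#'   (summing to 100).
#' @param histogram write a histogram section.
#' @param name file stem.
#' @return invisibly, list with `path`, `truth` and record.
#' @export
synthDlsExport <- function(dir, peaks = data.frame(
                             rh = c(1, 4, 60), pd_pct = c(40, 12, 35),
                             intensity_pct = c(20, 50, 30)),
                           histogram = TRUE, name = "dls_synth") {
  peaks <- as.data.frame(peaks)
  stopifnot(abs(sum(peaks$intensity_pct) - 100) < 1e-6)
  w <- peaks$intensity_pct / peaks$rh^3
  peaks$mass_pct <- 100 * w / sum(w)
  peaks$pd <- peaks$rh * peaks$pd_pct / 100
  lines <- c("Peak\tR (nm)\tPd (nm)\tPd (%)\tIntensity (%)\tMass (%)",
             sprintf("%d\t%s\t%s\t%s\t%s\t%s", seq_len(nrow(peaks)),
                     fmtNum(peaks$rh), fmtNum(peaks$pd),
                     fmtNum(peaks$pd_pct), fmtNum(peaks$intensity_pct),
                     fmtNum(peaks$mass_pct)))
  if (histogram) {
    rad <- exp(seq(log(0.5), log(100), length.out = 60))
    intens <- numeric(length(rad))
    for (i in seq_len(nrow(peaks))) {
      sdlog <- max(peaks$pd_pct[i], 5) / 100
      intens <- intens + peaks$intensity_pct[i] *
        exp(-(log(rad / peaks$rh[i]))^2 / (2 * sdlog^2))
    }
    lines <- c(lines, "", "Histogram",
               paste(fmtNum(rad), fmtNum(intens), sep = "\t"))
  }
  path <- file.path(dir, paste0(name, ".txt"))
  writeLines(lines, path)
  truth <- list(kind = "dls", peaks = peaks)
  tpath <- file.path(dir, paste0(name, "_truth.json"))
  writeTruth(truth, tpath)
  invisible(list(path = path, truth = tpath, record = truth))
}

#' Generate a synthetic training cohort with a planted rule
#'
#' Draws the six features from documented distributions -- `mw_mono`
#' lognormal around 40 kDa, `l_dis` geometric-like, `r_dsf`/`r_sec`/`p_maj`
#' beta-shaped, `yield` ordinal 0--5 -- then scores each sample by a planted
#' single-split rule on one feature plus clipped Gaussian noise, rounded to
#' the 0--6 scale.  Writes the cohort CSV and the generative truth.
#'
#' @param dir output directory. @param seed RNG seed.
#' @param n cohort size (>= 10).
#' @param rule list with `feature`, `threshold`, `lowScore`, `highScore`:
#'   samples with feature <= threshold get `lowScore`, others `highScore`
#'   (before noise).
#' @param sigma outcome noise standard deviation.
#' @param missingRate fraction of experimental feature values blanked to NA
#'   (sequence features are never blanked).
#' @param name file stem.
#' @return invisibly, list with `csv`, `truth` paths, the cohort data.frame
#'   and the truth record.
#' @export
synthCohort <- function(dir, seed = 1L, n = 100L,
                        rule = list(feature = "l_dis", threshold = 40,
                                    lowScore = 5, highScore = 0),
                        sigma = 0.5, missingRate = 0,
                        name = "cohort_synth") {
  stopifnot(n >= 10L)
  cohort <- withLocalSeed(seed, {
    df <- data.frame(
      r_dsf = rbeta(n, 2, 5),
      yield = sample(0:5, n, replace = TRUE),
      r_sec = rbeta(n, 1.5, 8),
      p_maj = rbeta(n, 6, 2),
      mw_mono = rlnorm(n, log(40000), 0.5),
      l_dis = rgeom(n, 1 / 30))
    raw <- ifelse(df[[rule$feature]] <= rule$threshold,
                  rule$lowScore, rule$highScore)
    df$score <- pmin(pmax(round(raw + rnorm(n, 0, sigma)), 0), 6)
    if (missingRate > 0) {
      for (f in c("r_dsf", "yield", "r_sec", "p_maj"))
        df[[f]][runif(n) < missingRate] <- NA
    }
    df
  })
  csv <- file.path(dir, paste0(name, ".csv"))
  write.csv(cohort, csv, row.names = FALSE)
  truth <- list(kind = "cohort", seed = seed, n = n, rule = rule,
                sigma = sigma, missing_rate = missingRate)
  tpath <- file.path(dir, paste0(name, "_truth.json"))
  writeTruth(truth, tpath)
  invisible(list(csv = csv, truth = tpath, cohort = cohort, record = truth))
}
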