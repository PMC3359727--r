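# Dynamic light scattering: peak-table parsing, major-peak selection,
# hydrodynamic radius -> molecular weight, oligomer ratio, Pmaj and the
# ordinal DLS homogeneity score.

#' Molecular weight from hydrodynamic radius
#'
#' Empirical globular-protein calibration `MW = (1.68 Rh)^2.3398` with Rh in
#' nm and MW in kDa, the relation commonly used by DLS vendor software.
#' Constants are configurable because calibrations differ between packages.
#'
#' @param rh hydrodynamic radius, nm (> 0).
#' @param a,b calibration constants.
#' @return estimated molecular weight, kDa.
#' @examples
#' mwFromRadius(3)   # ~44 kDa, a typical monomeric protein
#' @export
mwFromRadius <- function(rh, a = 1.68, b = 2.3398) {
  stopifnot(all(rh > 0))
  (a * rh)^b
}

#' Select the major DLS peak
#'
#' The highest-intensity peak with hydrodynamic radius in the 2--10 nm
#' window (the range where monomeric and small-oligomer proteins scatter).
#' When no peak qualifies, the global intensity maximum is used and flagged.
#' Equal intensities tie-break toward the smaller radius.
#'
#' @param peaks data.frame with columns `rh` and `intensity_pct`.
#' @param window radius window, nm.
#' @return integer index with attribute `fallback` (logical).
#' @export
selectMajorPeak <- function(peaks, window = c(2, 10)) {
  stopifnot(nrow(peaks) >= 1L)
  inWin <- which(peaks$rh >= window[1] & peaks$rh <= window[2])
  pool <- if (length(inWin)) inWin else seq_len(nrow(peaks))
  ord <- pool[order(-peaks$intensity_pct[pool], peaks$rh[pool])]
  structure(ord[1], fallback = length(inWin) == 0L)
}

#' Intensity fraction of the major peak (Pmaj)
#'
#' Ratio of the major peak's intensity to the total intensity of all peaks
#' excluding particles smaller than the major peak: `Pmaj = I_major /
#' sum(I_j : Rh_j >= Rh_major)`.  Smaller species (salts, small contaminants)
#' are excluded because they do not compete with the major species during
#' crystallization.
#'
#' @param peaks peak data.frame. @param majorIndex index of the major peak.
#' @return fraction in `(0, 1]`.
#' @export
pMaj <- function(peaks, majorIndex) {
  stopifnot(majorIndex >= 1L, majorIndex <= nrow(peaks))
  keep <- peaks$rh >= peaks$rh[majorIndex]
  peaks$intensity_pct[majorIndex] / sum(peaks$intensity_pct[keep])
}

#' Ordinal DLS homogeneity score
#'
#' Categorizes a DLS result by peak count and percent polydispersity:
#' 4 = single peak, \%Pd below `pdCut`; 3 = single peak otherwise;
#' 2 = multiple peaks but the major peak carries at least `majCut`\% of the
#' intensity; 1 = otherwise.  The rubric boundaries are configurable; the
#' score is reported for display and is not a default predictor input.
#'
#' @param peaks peak data.frame.
#' @param majorIndex major-peak index (default from [selectMajorPeak()]).
#' @param pdCut percent-polydispersity cutoff for a monodisperse call.
#' @param majCut major-peak intensity cutoff, percent.
#' @return integer 1--4.
#' @export
dlsScore <- function(peaks, majorIndex = NULL, pdCut = 15, majCut = 50) {
  stopifnot(nrow(peaks) >= 1L)
  if (is.null(majorIndex)) majorIndex <- as.integer(selectMajorPeak(peaks))
  if (nrow(peaks) == 1L) {
    if (peaks$pd_pct[1] < pdCut) 4L else 3L
  } else {
    if (peaks$intensity_pct[majorIndex] >= majCut) 2L else 1L
  }
}

#' Parse a DLS peak-table text export
#'
#' Reads vendor-style tab- or comma-delimited exports with one row per peak
#' and columns radius (nm), polydispersity (nm), \%Pd, \%intensity and
#' \%mass, plus an optional trailing histogram section (`Histogram` marker
#' followed by radius/intensity pairs).
#'
#' @param path text export.
#' @param monomerMW optional sequence-derived monomer MW in Da, used for the
#'   oligomer ratio.
#' @return a [DlsResult-class].
#' @export
readDlsExport <- function(path, monomerMW = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  histAt <- grep("^\\s*histogram\\b", lines, ignore.case = TRUE)
  peakLines <- if (length(histAt)) lines[seq_len(histAt[1] - 1L)] else lines
  rows <- list()
  for (i in seq_along(peakLines)) {
    f <- strsplit(trimws(peakLines[i]), "[,\t]+")[[1]]
    if (length(f) == 0L || !nzchar(f[1])) next
    num <- suppressWarnings(as.numeric(f))
    if (all(is.na(num))) next                       # header line
    if (length(f) < 6L || anyNA(num[2:6]))
      stop(sprintf("malformed DLS peak row at line %d", i))
    rows[[length(rows) + 1L]] <- num[2:6]
  }
  if (length(rows) == 0L) stop("no peaks found in DLS export")
  tab <- do.call(rbind, rows)
  peaks <- data.frame(rh = tab[, 1], pd = tab[, 2], pd_pct = tab[, 3],
                      intensity_pct = tab[, 4], mass_pct = tab[, 5])
  hist <- NULL
  if (length(histAt)) {
    hl <- lines[(histAt[1] + 1L):length(lines)]
    hv <- lapply(hl, function(l)
      suppressWarnings(as.numeric(strsplit(trimws(l), "[,\t ]+")[[1]])))
    hv <- hv[vapply(hv, function(v) length(v) >= 2 && !anyNA(v[1:2]),
                    logical(1))]
    if (length(hv))
      hist <- data.frame(radius = vapply(hv, `[`, numeric(1), 1L),
                         intensity = vapply(hv, `[`, numeric(1), 2L))
  }
  dlsResult(peaks, histogram = hist, monomerMW = monomerMW)
}

#' Assemble a DLS result from a peak table
#'
#' Computes radius-derived MW per peak, selects the major peak, and derives
#' the oligomer ratio, Pmaj and the DLS score.
#'
#' @param peaks data.frame with columns `rh`, `pd`, `pd_pct`,
#'   `intensity_pct`, `mass_pct`.
#' @param histogram optional data.frame (`radius`, `intensity`).
#' @param monomerMW sequence-derived monomer MW, Da (`NA` allowed).
#' @param majorIndex override for the major peak (default: rule-selected).
#' @return a [DlsResult-class].
#' @export
dlsResult <- function(peaks, histogram = NULL, monomerMW = NA_real_,
                      majorIndex = NULL) {
  peaks$mw_r <- mwFromRadius(peaks$rh)
  fallback <- FALSE
  if (is.null(majorIndex)) {
    sel <- selectMajorPeak(peaks)
    majorIndex <- as.integer(sel)
    fallback <- attr(sel, "fallback")
  }
  nOlig <- if (is.na(monomerMW)) NA_real_
           else peaks$mw_r[majorIndex] * 1000 / monomerMW
  new("DlsResult", peaks = peaks, histogram = histogram,
      majorIndex = as.integer(majorIndex), majorFallback = fallback,
      nOlig = nOlig, pMaj = pMaj(peaks, majorIndex),
      dlsScore = dlsScore(peaks, majorIndex))
}

#' @describeIn dlsResult the per-peak table (with derived `mw_r`, kDa).
#' @param x a [DlsResult-class].
#' @export
setMethod("peaks", "DlsResult", function(x) x@peaks)

#' @describeIn dlsResult intensity fraction of the major peak.
#' @export
setMethod("pMajor", "DlsResult", function(x) x@pMaj)

#' @describeIn dlsResult DLS-estimated MW of the major peak over the
#'   sequence monomer MW (about 1 for monomers, 2 for dimers); `NA` when no
#'   monomer MW was supplied.
#' @export
setMethod("oligomerRatio", "DlsResult", function(x) x@nOlig)

#' @describeIn dlsResult index of the major peak.
#' @export
setMethod("majorIndex", "DlsResult", function(x) x@majorIndex)

#' @describeIn dlsResult override the major peak; Pmaj, oligomer ratio and
#'   the DLS score are recomputed.  The monomer MW is recovered from the
#'   existing ratio when present.
#' @param value new major-peak index.
#' @export
setReplaceMethod("majorIndex", "DlsResult", function(x, value) {
  value <- as.integer(value)
  if (value < 1L || value > nrow(x@peaks)) stop("major peak index out of range")
  monomer <- if (is.na(x@nOlig)) NA_real_
             else x@peaks$mw_r[x@majorIndex] * 1000 / x@nOlig
  x@majorIndex <- value
  x@majorFallback <- FALSE
  x@pMaj <- pMaj(x@peaks, value)
  x@nOlig <- if (is.na(monomer)) NA_real_
             else x@peaks$mw_r[value] * 1000 / monomer
  x@dlsScore <- dlsScore(x@peaks, value)
  validObject(x)
  x
})

setMethod("show", "DlsResult", function(object) {
  cat(sprintf("DlsResult: %d peak%s%s\n", nrow(object@peaks),
              if (nrow(object@peaks) == 1) "" else "s",
              if (object@majorFallback) " (major peak outside 2-10 nm window)"
              else ""))
  p <- object@peaks
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %s Rh %.2f nm  %%Pd %.1f  %%I %.1f  %%mass %.1f  MW %.1f kDa\n",
                if (i == object@majorIndex) "*" else " ",
                p$rh[i], p$pd_pct[i], p$intensity_pct[i], p$mass_pct[i],
                p$mw_r[i]))
  cat(sprintf("  Pmaj %.3f  oligomer ratio %s  DLS score %d\n", object@pMaj,
              if (is.na(object@nOlig)) "NA" else sprintf("%.2f", object@nOlig),
              object@dlsScore))
})
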