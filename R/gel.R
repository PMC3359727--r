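# Gel-based scores: expression yield, limited-proteolysis stability and the
# stored (but predictor-unused) SDS-PAGE purity score.

#' Expression yield result
#'
#' @param visualScore ordinal 0--5 visual gel score (0 = none, 5 = extremely
#'   high, approximately 100 mg per liter of culture), or `NA`.
#' @param massMg mass of purified protein, mg, or `NA`.
#' @param cultureL culture volume, liters, or `NA`.
#' @return a [YieldResult-class].
#' @export
yieldResult <- function(visualScore = NA_real_, massMg = NA_real_,
                        cultureL = NA_real_) {
  mgPerL <- if (!is.na(massMg) && !is.na(cultureL)) massMg / cultureL
            else NA_real_
  new("YieldResult", visualScore = as.numeric(visualScore),
      massMg = as.numeric(massMg), cultureL = as.numeric(cultureL),
      mgPerL = mgPerL)
}

# Visual score 5 ("extremely high") corresponds to ~100 mg/L of culture.
YIELD_TOP_MG_PER_L <- 100

#' Yield value used by the predictor
#'
#' The visual gel score is used when provided; otherwise the calculated
#' milligrams per liter of culture.  The returned value carries a `kind`
#' attribute (`"visual"` or `"mg_per_l"`) and, for a visual score, an
#' `mg_per_l_equivalent` attribute that maps the top category to
#' approximately 100 mg/L (linear in score).
#'
#' @param y a [YieldResult-class].
#' @return the predictor yield value, or `NA` when neither input is present.
#' @export
effectiveYield <- function(y) {
  stopifnot(is(y, "YieldResult"))
  if (!is.na(y@visualScore)) {
    structure(y@visualScore, kind = "visual",
              mg_per_l_equivalent = y@visualScore / 5 * YIELD_TOP_MG_PER_L)
  } else if (!is.na(y@mgPerL)) {
    structure(y@mgPerL, kind = "mg_per_l")
  } else NA_real_
}

#' Limited-proteolysis stability score for one protease
#'
#' Scores persistence of the major gel band through timed digestion on the
#' 1 (unstable) to 5 (extremely stable) scale, from the estimated change in
#' band MW and the fraction of band intensity retained after 1 h and 24 h:
#' \itemize{
#'   \item 5: MW change <= 5\% and >= 90\% intensity retained at 24 h;
#'   \item 4: >= 90\% intact at 1 h and >= 50\% at 24 h;
#'   \item 3: >= 90\% at 1 h but < 50\% at 24 h (or no 24 h observation);
#'   \item 2: 10--90\% at 1 h;
#'   \item 1: < 10\% at 1 h.
#' }
#' The intermediate thresholds interpolate between the scale's defined
#' endpoints and are configurable via `cuts`.
#'
#' @param mwChange1h,mwChange24h fractional change in major-band MW (0 =
#'   unchanged); `NA` when not observed.
#' @param intensity1h,intensity24h fraction of band intensity retained.
#' @param cuts named list of rubric thresholds.
#' @return integer score 1--5, or `NA` when no timepoint was observed.
#' @export
lpProteaseScore <- function(mwChange1h = NA_real_, intensity1h = NA_real_,
                            mwChange24h = NA_real_, intensity24h = NA_real_,
                            cuts = list(intact = 0.90, partial = 0.50,
                                        gone = 0.10, mw = 0.05)) {
  has1h <- !is.na(intensity1h)
  has24h <- !is.na(intensity24h)
  if (!has1h && !has24h) return(NA_integer_)
  if (!has1h) { intensity1h <- intensity24h; mwChange1h <- mwChange24h }
  if (intensity1h < cuts$gone) return(1L)
  if (intensity1h < cuts$intact) return(2L)
  if (!has24h) return(3L)
  mwOk <- (is.na(mwChange1h) || abs(mwChange1h) <= cuts$mw) &&
          (is.na(mwChange24h) || abs(mwChange24h) <= cuts$mw)
  if (intensity24h >= cuts$intact && mwOk) return(5L)
  if (intensity24h >= cuts$partial) return(4L)
  3L
}

#' Mean limited-proteolysis stability over proteases
#'
#' @param scores integer vector of per-protease scores (1--5).
#' @param proteases optional protease names.
#' @return an [LpResult-class] with the unrounded mean stability.
#' @export
lpStability <- function(scores, proteases = NULL) {
  scores <- as.integer(scores)
  if (is.null(proteases)) proteases <- paste0("protease", seq_along(scores))
  new("LpResult",
      perProtease = data.frame(protease = proteases, score = scores),
      stability = mean(scores))
}

#' SDS-PAGE purity score
#'
#' Visual purity score on a 0--5 scale, stored and serialized for record
#' keeping and sharing.  It does not enter the default feature vector: the
#' outcome data behind the shipped predictor lacked poorly pure samples
#' (they were dropped before crystallization trials), so the score carries
#' no usable signal there.
#'
#' @param visualScore ordinal 0--5.
#' @return an `sds`-tagged [ExperimentSummary-class].
#' @export
sdsPurityScore <- function(visualScore) {
  stopifnot(visualScore >= 0, visualScore <= 5)
  experimentSummary("sds", c(purity_score = as.numeric(visualScore)),
                    provenance = "manual")
}

setMethod("show", "YieldResult", function(object) {
  v <- effectiveYield(object)
  cat(sprintf("YieldResult: %s\n",
              if (is.na(v)) "no data"
              else if (attr(v, "kind") == "visual")
                sprintf("visual score %g (~%g mg/L)", as.numeric(v),
                        attr(v, "mg_per_l_equivalent"))
              else sprintf("%.3g mg per liter of culture", as.numeric(v))))
})

setMethod("show", "LpResult", function(object) {
  cat(sprintf("LpResult: stability %.3g over %d protease(s)\n",
              object@stability, nrow(object@perProtease)))
})
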