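# S4 classes for the experiment fits, the sample container and the predictor.

EXPERIMENT_TAGS <- c("seq", "dsf", "sec", "dls", "yield", "sds", "lp")

# Canonical predictor feature order used throughout the package.
FEATURE_NAMES <- c("r_dsf", "yield", "r_sec", "p_maj", "mw_mono", "l_dis")

#' Differential scanning fluorimetry melt curve
#'
#' One well's fluorescence-versus-temperature trace.  Temperatures are stored
#' in Kelvin (Celsius input is converted on parsing) and must be strictly
#' increasing.
#'
#' @slot wellLabel single well identifier, e.g. `"A1"`.
#' @slot temperature numeric vector, Kelvin.
#' @slot fluorescence numeric vector, arbitrary units.
#' @exportClass DsfCurve
setClass("DsfCurve",
  representation(wellLabel = "character",
                 temperature = "numeric",
                 fluorescence = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@temperature) != length(object@fluorescence))
      msg <- c(msg, "temperature and fluorescence must have equal length")
    if (length(object@temperature) < 10L)
      msg <- c(msg, "curve must have at least 10 points")
    if (any(diff(object@temperature) <= 0))
      msg <- c(msg, "temperature must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' Fitted Boltzmann melt model
#'
#' Result of fitting `F(T) = baseline + sum_j dF_j / (1 + exp((Tm_j - T)/s_j))`
#' to the truncated region of a [DsfCurve-class].  The `transitions` table has
#' one row per transition with columns `tm`, `s`, `delta_f` and the derived
#' `max_slope = delta_f/(4 s)` and `fwhm = 2 ln(3 + 2 sqrt(2)) s` (full width
#' at half maximum of dF/dT).  The predictor value `rDsf` is the fitted
#' fluorescence at 303.15 K divided by the fitted fluorescence at the major
#' transition midpoint.
#'
#' @slot baseline additive fluorescence baseline.
#' @slot transitions data.frame of per-transition parameters, sorted by `tm`.
#' @slot majorIndex row index of the major (steepest) transition;
#'   user-overridable via [setMajorTransition()].
#' @slot f30,fTm fitted fluorescence at 303.15 K and at the major midpoint.
#' @slot rDsf dimensionless ratio `f30 / fTm`.
#' @slot fitRegion integer range (first, last index) of the fitted region.
#' @slot rss residual sum of squares over the fitted region.
#' @slot curve the source curve (kept for display; may be `NULL` after
#'   round-tripping summaries through XML).
#' @slot converged logical; `FALSE` marks a best-effort fit that hit the
#'   restart bound.
#' @exportClass DsfFit
setClass("DsfFit",
  representation(baseline = "numeric",
                 transitions = "data.frame",
                 majorIndex = "integer",
                 f30 = "numeric",
                 fTm = "numeric",
                 rDsf = "numeric",
                 fitRegion = "integer",
                 rss = "numeric",
                 curve = "ANY",
                 converged = "logical"),
  validity = function(object) {
    msg <- character(0)
    k <- nrow(object@transitions)
    if (k < 1L) msg <- c(msg, "at least one transition required")
    if (object@majorIndex < 1L || object@majorIndex > k)
      msg <- c(msg, "majorIndex out of range")
    if (any(object@transitions$s <= 0))
      msg <- c(msg, "slope parameter s must be positive")
    fw <- 2 * log(3 + 2 * sqrt(2)) * object@transitions$s
    if (any(abs(object@transitions$fwhm - fw) > 1e-9 * abs(fw)))
      msg <- c(msg, "fwhm must equal 2 ln(3+2*sqrt(2)) * s")
    if (!is.na(object@rDsf) && object@rDsf <= 0)
      msg <- c(msg, "rDsf must be positive")
    if (length(msg)) msg else TRUE
  })

#' Size-exclusion chromatogram in fraction coordinates
#'
#' Absorbance trace with the x axis converted from time or volume to
#' continuous fraction coordinates: `frac(t) = 1 + (t - collectionStart) *
#' flowRate / fractionSize`.  The integer fraction index of a point is
#' `floor(frac)` (half-open volume intervals, 1-based); points collected
#' before `collectionStart` belong to fraction 0.
#'
#' @slot fraction continuous fraction coordinate, nondecreasing.
#' @slot absorbance milli-absorbance units.
#' @slot flowRate mL/min. @slot fractionSize mL. @slot collectionStart min.
#' @exportClass SecChromatogram
setClass("SecChromatogram",
  representation(fraction = "numeric",
                 absorbance = "numeric",
                 flowRate = "numeric",
                 fractionSize = "numeric",
                 collectionStart = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fraction) != length(object@absorbance))
      msg <- c(msg, "fraction and absorbance must have equal length")
    if (is.unsorted(object@fraction))
      msg <- c(msg, "fraction axis must be nondecreasing")
    if (object@flowRate <= 0) msg <- c(msg, "flowRate must be positive")
    if (object@fractionSize <= 0) msg <- c(msg, "fractionSize must be positive")
    if (length(msg)) msg else TRUE
  })

#' Gaussian mixture fit of a chromatogram
#'
#' @slot components data.frame with columns `height` (mAU), `center`
#'   (fraction) and `width` (fraction sigma), sorted by center.
#' @slot poolRange first and last pooled fraction (inclusive), or `NA`.
#' @slot purityPool percent purity of the pooled fractions, or `NA`.
#' @slot rSec single-Gaussian residual fraction RSS1/TSS in `[0, 1]`, or `NA`;
#'   always computed from a separate one-component fit.
#' @slot rss residual sum of squares of the mixture fit, mAU^2.
#' @exportClass SecFit
setClass("SecFit",
  representation(components = "data.frame",
                 poolRange = "numeric",
                 purityPool = "numeric",
                 rSec = "numeric",
                 rss = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (any(object@components$width <= 0))
      msg <- c(msg, "component widths must be positive")
    if (!is.na(object@purityPool) &&
        (object@purityPool < 0 || object@purityPool > 100))
      msg <- c(msg, "purityPool must lie in [0, 100]")
    if (!is.na(object@rSec) && (object@rSec < 0 || object@rSec > 1))
      msg <- c(msg, "rSec must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Dynamic light scattering result
#'
#' Peak table plus derived quantities.  `peaks` has one row per peak with
#' columns `rh` (nm), `pd` (nm), `pd_pct`, `intensity_pct`, `mass_pct` and the
#' radius-derived `mw_r` (kDa).
#'
#' @slot peaks per-peak data.frame (see above).
#' @slot histogram optional data.frame with `radius` and `intensity`, or `NULL`.
#' @slot majorIndex row index of the major peak (user-overridable).
#' @slot majorFallback `TRUE` when no peak fell in the 2--10 nm window and the
#'   global intensity maximum was used instead.
#' @slot nOlig oligomer ratio `mw_r(major) / mw_mono`, or `NA` when no monomer
#'   mass was supplied.
#' @slot pMaj intensity fraction of the major peak among peaks at least as
#'   large as it.
#' @slot dlsScore ordinal homogeneity score 1--4.
#' @exportClass DlsResult
setClass("DlsResult",
  representation(peaks = "data.frame",
                 histogram = "ANY",
                 majorIndex = "integer",
                 majorFallback = "logical",
                 nOlig = "numeric",
                 pMaj = "numeric",
                 dlsScore = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@peaks) < 1L) msg <- c(msg, "at least one peak required")
    if (any(object@peaks$rh <= 0)) msg <- c(msg, "rh must be positive")
    pct <- c(object@peaks$pd_pct, object@peaks$intensity_pct,
             object@peaks$mass_pct)
    if (any(pct < 0 | pct > 100, na.rm = TRUE))
      msg <- c(msg, "percentages must lie in [0, 100]")
    if (abs(sum(object@peaks$intensity_pct) - 100) > 1)
      msg <- c(msg, "intensity percentages must sum to 100 within 1%")
    if (object@majorIndex < 1L || object@majorIndex > nrow(object@peaks))
      msg <- c(msg, "majorIndex out of range")
    if (!is.na(object@pMaj) && (object@pMaj <= 0 || object@pMaj > 1))
      msg <- c(msg, "pMaj must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

#' A protein sequence with optional per-residue disorder calls
#'
#' @slot id sequence identifier.
#' @slot residues uppercase one-letter amino-acid string (20 standard + X).
#' @slot disorderCalls optional logical vector, one call per residue, or `NULL`.
#' @slot disorderSource `"user"`, `"fallback"` (heuristic, not DisEMBL) or
#'   `"none"`.
#' @exportClass SequenceRecord
setClass("SequenceRecord",
  representation(id = "character",
                 residues = "character",
                 disorderCalls = "ANY",
                 disorderSource = "character"),
  validity = function(object) {
    msg <- character(0)
    res <- object@residues
    bad <- regmatches(res, regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", res))
    if (length(bad) && nzchar(bad))
      msg <- c(msg, sprintf("illegal residue character '%s'", bad))
    if (!is.null(object@disorderCalls) &&
        length(object@disorderCalls) != nchar(res))
      msg <- c(msg, "disorderCalls must have one entry per residue")
    if (!object@disorderSource %in% c("user", "fallback", "none"))
      msg <- c(msg, "disorderSource must be user/fallback/none")
    if (length(msg)) msg else TRUE
  })

#' Summary of one experiment for one sample
#'
#' Holds the per-type summary values used for display and prediction, with
#' provenance `"parsed"` (derived from a raw file, full fit object attached as
#' payload) or `"manual"` (values typed in, no payload).
#'
#' @slot typeTag one of `seq, dsf, sec, dls, yield, sds, lp`.
#' @slot summaryValues named numeric vector; names must belong to the schema
#'   registered for `typeTag` (see [summarySchema()]).
#' @slot provenance `"parsed"` or `"manual"`.
#' @slot payload the full fit/result object, or `NULL`.
#' @exportClass ExperimentSummary
setClass("ExperimentSummary",
  representation(typeTag = "character",
                 summaryValues = "numeric",
                 provenance = "character",
                 payload = "ANY"),
  validity = function(object) {
    msg <- character(0)
    if (!object@typeTag %in% EXPERIMENT_TAGS)
      msg <- c(msg, sprintf("unknown experiment tag '%s'", object@typeTag))
    if (!object@provenance %in% c("parsed", "manual"))
      msg <- c(msg, "provenance must be 'parsed' or 'manual'")
    if (object@provenance == "manual" && !is.null(object@payload))
      msg <- c(msg, "manual provenance implies no payload")
    schema <- summarySchema(object@typeTag)
    bad <- setdiff(names(object@summaryValues), schema)
    if (length(bad))
      msg <- c(msg, sprintf("summary value '%s' not in schema for '%s'",
                            bad[1], object@typeTag))
    if (length(msg)) msg else TRUE
  })

#' A sample: sequences plus experiment results
#'
#' The central container.  `results` maps each experiment-type tag to a list
#' of [ExperimentSummary-class] objects; `selection` maps each tag to the
#' indices of results currently selected for prediction (defaults to all).
#' A sample with zero results is valid (data status "missing").
#'
#' @slot name short identifier. @slot description free text.
#' @slot sequences list of [SequenceRecord-class].
#' @slot results named list (by tag) of lists of [ExperimentSummary-class].
#' @slot selection named list (by tag) of integer index vectors.
#' @exportClass ProteinSample
setClass("ProteinSample",
  representation(name = "character",
                 description = "character",
                 sequences = "list",
                 results = "list",
                 selection = "list"),
  prototype(description = "", sequences = list(),
            results = structure(list(), names = character(0)),
            selection = structure(list(), names = character(0))),
  validity = function(object) {
    msg <- character(0)
    badTag <- setdiff(names(object@results), EXPERIMENT_TAGS)
    if (length(badTag))
      msg <- c(msg, sprintf("unknown experiment tag '%s'", badTag[1]))
    for (tag in names(object@selection)) {
      sel <- object@selection[[tag]]
      n <- length(object@results[[tag]])
      if (length(sel) && (any(sel < 1L) || any(sel > n)))
        msg <- c(msg, sprintf("selection for '%s' out of range", tag))
    }
    if (length(msg)) msg else TRUE
  })

#' The six predictor inputs for one sample
#'
#' Ordered named values `r_dsf`, `yield`, `r_sec`, `p_maj`, `mw_mono`,
#' `l_dis`; `NA` marks a missing feature (the missing mask).  Missing values
#' are never imputed here -- routing of missing features is the predictor's
#' concern.
#'
#' @slot values named numeric of length 6 in canonical feature order.
#' @exportClass FeatureVector
setClass("FeatureVector",
  representation(values = "numeric"),
  validity = function(object) {
    msg <- character(0)
    v <- object@values
    if (!identical(names(v), FEATURE_NAMES))
      msg <- c(msg, "values must be named r_dsf, yield, r_sec, p_maj, mw_mono, l_dis")
    if (!is.na(v["p_maj"]) && (v["p_maj"] < 0 || v["p_maj"] > 1))
      msg <- c(msg, "p_maj must lie in [0, 1]")
    if (!is.na(v["r_sec"]) && (v["r_sec"] < 0 || v["r_sec"] > 1))
      msg <- c(msg, "r_sec must lie in [0, 1]")
    if (!is.na(v["mw_mono"]) && v["mw_mono"] <= 0)
      msg <- c(msg, "mw_mono must be positive")
    if (!is.na(v["l_dis"]) && v["l_dis"] < 0)
      msg <- c(msg, "l_dis must be nonnegative")
    if (length(msg)) msg else TRUE
  })

#' Recursive regression partition tree
#'
#' Binary tree over the six-feature vector predicting the mean diffraction
#' score of training samples routed to each leaf.  Internal nodes carry
#' `(feature, threshold, missing-route)`; every node stores the mean and the
#' score histogram of its routed training samples, so leaf payloads are exact
#' by construction.
#'
#' @slot root recursive node list (see [writeTreeJson()] for the layout).
#' @slot params training parameters (`minLeaf`, `maxDepth`).
#' @slot features feature names the tree may split on.
#' @exportClass RegressionTree
setClass("RegressionTree",
  representation(root = "list", params = "list", features = "character"))

#' A prediction for one sample
#'
#' @slot meanScore mean diffraction score of co-routed training samples.
#' @slot interpretation text band for `meanScore` (see [interpretScore()]).
#' @slot trainHist,testHist counts over scores 0--6 at the leaf.
#' @slot path data.frame of the splits taken: `feature`, `threshold`,
#'   `direction` (`"le"`/`"gt"`), `favorable` (logical, `NA` = neutral),
#'   `imputed` (`TRUE` when the feature was missing and the stored
#'   missing-route was followed).
#' @slot leafN number of training samples at the leaf.
#' @exportClass CrystalPrediction
setClass("CrystalPrediction",
  representation(meanScore = "numeric",
                 interpretation = "character",
                 trainHist = "numeric",
                 testHist = "numeric",
                 path = "data.frame",
                 leafN = "integer"))

#' Expression yield result
#'
#' Either a visual gel score on the 0--5 ordinal scale (0 = none, 5 =
#' extremely high, approximately 100 mg per liter of culture) or a numeric
#' mass of purified protein and culture volume, or both.
#'
#' @slot visualScore ordinal 0--5 or `NA`.
#' @slot massMg mg purified protein or `NA`. @slot cultureL liters or `NA`.
#' @slot mgPerL derived `massMg / cultureL`, `NA` when inputs absent.
#' @exportClass YieldResult
setClass("YieldResult",
  representation(visualScore = "numeric", massMg = "numeric",
                 cultureL = "numeric", mgPerL = "numeric"),
  validity = function(object) {
    msg <- character(0)
    numericPair <- !is.na(object@massMg) && !is.na(object@cultureL)
    if (is.na(object@visualScore) && !numericPair)
      msg <- c(msg, "need a visual score or both massMg and cultureL")
    if (!is.na(object@visualScore) &&
        (object@visualScore < 0 || object@visualScore > 5))
      msg <- c(msg, "visualScore must lie in 0..5")
    if (numericPair &&
        !isTRUE(all.equal(object@mgPerL, object@massMg / object@cultureL)))
      msg <- c(msg, "mgPerL must equal massMg / cultureL")
    if (length(msg)) msg else TRUE
  })

#' Limited proteolysis result
#'
#' @slot perProtease data.frame with columns `protease` and `score` (1--5).
#' @slot stability unrounded mean of the per-protease scores.
#' @exportClass LpResult
setClass("LpResult",
  representation(perProtease = "data.frame", stability = "numeric"),
  validity = function(object) {
    msg <- character(0)
    sc <- object@perProtease$score
    if (length(sc) < 1L) msg <- c(msg, "at least one protease score required")
    if (any(!sc %in% 1:5)) msg <- c(msg, "scores must be integers in 1..5")
    if (abs(object@stability - mean(sc)) > 1e-12)
      msg <- c(msg, "stability must be the mean of the per-protease scores")
    if (length(msg)) msg else TRUE
  })
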