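# Sample/result organization: experiment summaries, selection, aggregation
# by mean, feature-vector assembly, and a thin JSON project manifest.

SUMMARY_SCHEMAS <- list(
  seq   = c("mw_mono", "gravy", "l_dis"),
  dsf   = c("tm", "s", "delta_f", "max_slope", "fwhm", "r_dsf"),
  sec   = c("r_sec", "purity_pool"),
  dls   = c("rh", "pd_pct", "intensity_pct", "mass_pct", "mw_r", "n_olig",
            "p_maj", "dls_score"),
  yield = c("yield", "visual_score", "mg_per_l"),
  sds   = c("purity_score"),
  lp    = c("stability"))

#' Summary-value schema for an experiment type
#'
#' @param tag experiment-type tag (`seq, dsf, sec, dls, yield, sds, lp`).
#' @return character vector of permitted summary-value names.
#' @export
summarySchema <- function(tag) {
  if (!tag %in% names(SUMMARY_SCHEMAS))
    stop(sprintf("unknown experiment tag '%s'", tag))
  SUMMARY_SCHEMAS[[tag]]
}

#' Create an experiment summary
#'
#' Used both for parsed results (attach the fit object as `payload`) and for
#' manual entry of summary values when raw files are unavailable (manual
#' provenance carries no payload).
#'
#' @param typeTag experiment-type tag.
#' @param summaryValues named numeric vector; names must belong to
#'   [summarySchema()] for the tag.
#' @param provenance `"parsed"` or `"manual"`.
#' @param payload full fit object for parsed results, else `NULL`.
#' @return an [ExperimentSummary-class].
#' @export
experimentSummary <- function(typeTag, summaryValues,
                              provenance = c("parsed", "manual"),
                              payload = NULL) {
  provenance <- match.arg(provenance)
  new("ExperimentSummary", typeTag = typeTag,
      summaryValues = summaryValues, provenance = provenance,
      payload = payload)
}

# Summary extraction from fit objects ------------------------------------

#' Summarize a fit object as an experiment result
#'
#' Converts a module's fit object ([DsfFit-class], [SecFit-class],
#' [DlsResult-class], [YieldResult-class], [LpResult-class] or a
#' [SequenceRecord-class]) into an [ExperimentSummary-class] carrying the
#' predictor/display values for its type, with the fit attached as payload.
#'
#' @param x a fit/result object.
#' @return an [ExperimentSummary-class].
#' @export
summarizeResult <- function(x) {
  if (is(x, "DsfFit")) {
    tr <- x@transitions[x@majorIndex, ]
    experimentSummary("dsf",
      c(tm = tr$tm, s = tr$s, delta_f = tr$delta_f,
        max_slope = tr$max_slope, fwhm = tr$fwhm, r_dsf = x@rDsf),
      payload = x)
  } else if (is(x, "SecFit")) {
    vals <- c(r_sec = x@rSec)
    if (!is.na(x@purityPool)) vals <- c(vals, purity_pool = x@purityPool)
    experimentSummary("sec", vals, payload = x)
  } else if (is(x, "DlsResult")) {
    p <- x@peaks[x@majorIndex, ]
    vals <- c(rh = p$rh, pd_pct = p$pd_pct, intensity_pct = p$intensity_pct,
              mass_pct = p$mass_pct, mw_r = p$mw_r, p_maj = x@pMaj,
              dls_score = as.numeric(x@dlsScore))
    if (!is.na(x@nOlig)) vals <- c(vals, n_olig = x@nOlig)
    experimentSummary("dls", vals, payload = x)
  } else if (is(x, "YieldResult")) {
    ey <- effectiveYield(x)
    vals <- c(yield = as.numeric(ey))
    if (!is.na(x@visualScore)) vals <- c(vals, visual_score = x@visualScore)
    if (!is.na(x@mgPerL)) vals <- c(vals, mg_per_l = x@mgPerL)
    experimentSummary("yield", vals, payload = x)
  } else if (is(x, "LpResult")) {
    experimentSummary("lp", c(stability = x@stability), payload = x)
  } else if (is(x, "SequenceRecord")) {
    f <- sequenceFeatures(x)
    experimentSummary("seq",
      c(mw_mono = f$mw_mono, gravy = f$gravy, l_dis = as.numeric(f$l_dis)),
      payload = x)
  } else stop("no summary rule for objects of class ", class(x)[1])
}

# Sample construction and editing -----------------------------------------

#' Create a protein sample
#'
#' @param name short identifier. @param description free text.
#' @param sequences list of [SequenceRecord-class] (or a single record).
#' @return a [ProteinSample-class] with no results (data status "missing").
#' @export
proteinSample <- function(name, description = "", sequences = list()) {
  if (is(sequences, "SequenceRecord")) sequences <- list(sequences)
  new("ProteinSample", name = name, description = description,
      sequences = sequences)
}

#' @describeIn proteinSample attach a result to a sample.  `result` may be an
#'   [ExperimentSummary-class] or any fit object accepted by
#'   [summarizeResult()]; newly added results are selected for prediction by
#'   default (`select = FALSE` to add unselected).
#' @param sample a [ProteinSample-class]. @param result result to attach.
#' @param select include the new result in the selection.
#' @export
setMethod("addResult", "ProteinSample", function(sample, result,
                                                 select = TRUE) {
  if (!is(result, "ExperimentSummary")) result <- summarizeResult(result)
  tag <- result@typeTag
  cur <- sample@results[[tag]]
  if (is.null(cur)) cur <- list()
  cur[[length(cur) + 1L]] <- result
  sample@results[[tag]] <- cur
  sel <- sample@selection[[tag]]
  if (is.null(sel)) sel <- integer(0)
  if (select) sel <- c(sel, length(cur))
  sample@selection[[tag]] <- as.integer(sel)
  validObject(sample)
  sample
})

#' @describeIn proteinSample replace the selected result indices for one
#'   experiment type.
#' @param tag experiment-type tag. @param indices integer result indices.
#' @export
setMethod("selectResults", "ProteinSample", function(sample, tag, indices) {
  if (!tag %in% EXPERIMENT_TAGS) stop("unknown experiment tag ", tag)
  sample@selection[[tag]] <- as.integer(indices)
  validObject(sample)
  sample
})

# Aggregation and feature assembly ----------------------------------------

#' Aggregate selected results by mean
#'
#' When more than one result of an experiment type is selected, the sample
#' summary (and the predictor) uses the arithmetic mean of each summary
#' value over the selected results.  An empty selection yields `NULL` (a
#' missing marker, never zero).
#'
#' @param results list of [ExperimentSummary-class] sharing one type tag.
#' @param selection integer indices of the selected results.
#' @return an aggregated [ExperimentSummary-class], or `NULL`.
#' @export
aggregateSelected <- function(results, selection) {
  if (length(selection) == 0L || length(results) == 0L) return(NULL)
  if (any(selection < 1L) || any(selection > length(results)))
    stop("selection index out of range")
  picked <- results[selection]
  tags <- unique(vapply(picked, function(r) r@typeTag, character(1)))
  if (length(tags) != 1L)
    stop("cannot aggregate results with mixed experiment tags: ",
         paste(tags, collapse = ", "))
  if (length(picked) == 1L) return(picked[[1]])
  keys <- unique(unlist(lapply(picked, function(r) names(r@summaryValues))))
  agg <- vapply(keys, function(k) {
    v <- unlist(lapply(picked, function(r) r@summaryValues[k]))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  names(agg) <- keys
  experimentSummary(tags, agg, provenance = "manual")
}

selectedSummary <- function(sample, tag) {
  aggregateSelected(sample@results[[tag]],
                    sample@selection[[tag]])
}

#' Construct a feature vector directly
#'
#' @param r_dsf,yield,r_sec,p_maj,mw_mono,l_dis feature values (`NA` =
#'   missing).
#' @return a [FeatureVector-class].
#' @export
featureVector <- function(r_dsf = NA_real_, yield = NA_real_,
                          r_sec = NA_real_, p_maj = NA_real_,
                          mw_mono = NA_real_, l_dis = NA_real_) {
  v <- c(r_dsf = as.numeric(r_dsf), yield = as.numeric(yield),
         r_sec = as.numeric(r_sec), p_maj = as.numeric(p_maj),
         mw_mono = as.numeric(mw_mono), l_dis = as.numeric(l_dis))
  new("FeatureVector", values = v)
}

#' @describeIn featureVector assemble the predictor inputs from a sample:
#'   sequence features are the maximum over the sample's sequences
#'   (multi-protein samples use the maximum molecular weight and maximum
#'   disorder stretch); experimental features come from
#'   [aggregateSelected()] per type; absent experiments stay `NA` in the
#'   missing mask.  A sample without sequences is rejected -- the monomer MW
#'   is mandatory for the predictor.
#' @param sample a [ProteinSample-class].
#' @param ... unused.
#' @export
setMethod("assembleFeatureVector", "ProteinSample", function(sample, ...) {
  if (length(sample@sequences) == 0L)
    stop("sample has no sequence: monomer MW is required for prediction")
  mw <- max(vapply(sample@sequences, monomerMW, numeric(1)))
  ld <- max(vapply(sample@sequences, function(s)
    longestDisorderStretch(disorderCallsFor(s)), integer(1)))
  pick <- function(tag, key) {
    s <- selectedSummary(sample, tag)
    if (is.null(s)) return(NA_real_)
    v <- s@summaryValues[key]
    if (is.null(v) || length(v) == 0L) NA_real_ else unname(v)
  }
  featureVector(r_dsf = pick("dsf", "r_dsf"),
                yield = pick("yield", "yield"),
                r_sec = pick("sec", "r_sec"),
                p_maj = pick("dls", "p_maj"),
                mw_mono = mw, l_dis = as.numeric(ld))
})

#' @describeIn featureVector the named feature values (`NA` = missing).
#' @param x a [FeatureVector-class].
#' @export
setMethod("featureValues", "FeatureVector", function(x) x@values)

#' @describeIn featureVector logical mask, `TRUE` exactly where a feature is
#'   missing.
#' @export
setMethod("missingMask", "FeatureVector", function(x) is.na(x@values))

#' @export
setMethod("typeTag", "ExperimentSummary", function(x) x@typeTag)

#' @export
setMethod("summaryValues", "ExperimentSummary", function(x) x@summaryValues)

setMethod("show", "ExperimentSummary", function(object) {
  cat(sprintf("ExperimentSummary [%s, %s]: %s\n", object@typeTag,
              object@provenance,
              paste(sprintf("%s=%.6g", names(object@summaryValues),
                            object@summaryValues), collapse = "  ")))
})

setMethod("show", "FeatureVector", function(object) {
  v <- object@values
  cat("FeatureVector:\n")
  for (nm in names(v))
    cat(sprintf("  %-8s %s\n", nm,
                if (is.na(v[nm])) "missing" else sprintf("%.6g", v[nm])))
})

setMethod("show", "ProteinSample", function(object) {
  cat(sprintf("ProteinSample '%s': %d sequence(s)\n", object@name,
              length(object@sequences)))
  for (tag in EXPERIMENT_TAGS) {
    n <- length(object@results[[tag]])
    if (n > 0L)
      cat(sprintf("  %-6s %d result(s), selected: %s\n", tag, n,
                  paste(object@selection[[tag]], collapse = ",")))
  }
})

# Project manifest ---------------------------------------------------------

#' Write / read a project manifest
#'
#' A project is a thin JSON manifest on disk: project name and description,
#' plus for each sample its name, description, FASTA path(s) and the paths
#' of its standardized-XML result files.  No database is involved.
#'
#' @param manifest list with elements `name`, `description`, `samples` (each
#'   sample a list with `name`, `description`, `fasta`, `results`).
#' @param path JSON file path.
#' @return `readProjectManifest` returns the manifest list.
#' @export
writeProjectManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeProjectManifest
#' @export
readProjectManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
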