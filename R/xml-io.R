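# Standardized XML interchange: the single format every parser writes and
# the analysis/prediction layers read.
#
# Layout:
#   <protchar_result type="dsf" version="1.0">
#     <metadata><meta name="...">...</meta></metadata>
#     <series name="temperature" unit="K">v1 v2 ...</series>   (optional)
#     <analysis><value name="tm">323.1</value>...</analysis>
#     <fit .../> | <peaks .../>                                 (payload)
#   </protchar_result>
# Numbers are serialized with 15 significant digits so summary values
# round-trip losslessly at (beyond) the guaranteed 9 significant digits.

XML_FORMAT_VERSION <- "1.0"

#' Write an experiment result to standardized XML
#'
#' Serializes an [ExperimentSummary-class] -- summary values plus, for
#' parsed provenance, the full fit payload ([DsfFit-class], [SecFit-class],
#' [DlsResult-class], [YieldResult-class], [LpResult-class] or
#' [SequenceRecord-class]) -- into the package's interchange XML.
#' `readStandardXml(writeStandardXml(x, f))` reproduces every field.
#'
#' @param summary an [ExperimentSummary-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeStandardXml <- function(summary, path) {
  stopifnot(is(summary, "ExperimentSummary"))
  validObject(summary)
  doc <- xml2::xml_new_root("protchar_result", type = summary@typeTag,
                            version = XML_FORMAT_VERSION)
  meta <- xml2::xml_add_child(doc, "metadata")
  mnode <- xml2::xml_add_child(meta, "meta", name = "provenance")
  xml2::xml_text(mnode) <- summary@provenance
  ana <- xml2::xml_add_child(doc, "analysis")
  sv <- summary@summaryValues
  for (nm in names(sv)) {
    v <- xml2::xml_add_child(ana, "value", name = nm)
    xml2::xml_text(v) <- fmtNum(sv[[nm]])
  }
  if (!is.null(summary@payload))
    writePayloadXml(doc, summary@payload)
  xml2::write_xml(doc, path)
  invisible(path)
}

addSeries <- function(parent, name, values, unit = NULL) {
  s <- if (is.null(unit)) xml2::xml_add_child(parent, "series", name = name)
       else xml2::xml_add_child(parent, "series", name = name, unit = unit)
  xml2::xml_text(s) <- paste(fmtNum(values), collapse = " ")
  s
}

readSeries <- function(doc, name) {
  node <- xml2::xml_find_first(doc, sprintf(".//series[@name='%s']", name))
  if (inherits(node, "xml_missing")) return(NULL)
  as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
}

writePayloadXml <- function(doc, payload) {
  if (is(payload, "DsfFit")) {
    fit <- xml2::xml_add_child(doc, "fit",
      baseline = fmtNum(payload@baseline),
      major_index = as.character(payload@majorIndex),
      f30 = fmtNum(payload@f30), f_tm = fmtNum(payload@fTm),
      r_dsf = fmtNum(payload@rDsf),
      region_first = as.character(payload@fitRegion[1]),
      region_last = as.character(payload@fitRegion[2]),
      rss = fmtNum(payload@rss))
    for (j in seq_len(nrow(payload@transitions)))
      xml2::xml_add_child(fit, "transition",
        tm = fmtNum(payload@transitions$tm[j]),
        s = fmtNum(payload@transitions$s[j]),
        delta_f = fmtNum(payload@transitions$delta_f[j]))
    if (!is.null(payload@curve)) {
      addSeries(doc, "temperature", payload@curve@temperature, unit = "K")
      addSeries(doc, "fluorescence", payload@curve@fluorescence)
      meta <- xml2::xml_find_first(doc, ".//metadata")
      w <- xml2::xml_add_child(meta, "meta", name = "well")
      xml2::xml_text(w) <- payload@curve@wellLabel
    }
  } else if (is(payload, "SecFit")) {
    fit <- xml2::xml_add_child(doc, "fit",
      rss = fmtNum(payload@rss), r_sec = fmtNum(payload@rSec),
      purity_pool = fmtNum(payload@purityPool),
      pool_first = fmtNum(payload@poolRange[1]),
      pool_last = fmtNum(payload@poolRange[2]))
    for (i in seq_len(nrow(payload@components)))
      xml2::xml_add_child(fit, "component",
        height = fmtNum(payload@components$height[i]),
        center = fmtNum(payload@components$center[i]),
        width = fmtNum(payload@components$width[i]))
  } else if (is(payload, "DlsResult")) {
    pk <- xml2::xml_add_child(doc, "peaks",
      major_index = as.character(payload@majorIndex),
      major_fallback = as.character(payload@majorFallback),
      n_olig = fmtNum(payload@nOlig), p_maj = fmtNum(payload@pMaj),
      dls_score = as.character(payload@dlsScore))
    for (i in seq_len(nrow(payload@peaks)))
      xml2::xml_add_child(pk, "peak",
        rh = fmtNum(payload@peaks$rh[i]), pd = fmtNum(payload@peaks$pd[i]),
        pd_pct = fmtNum(payload@peaks$pd_pct[i]),
        intensity_pct = fmtNum(payload@peaks$intensity_pct[i]),
        mass_pct = fmtNum(payload@peaks$mass_pct[i]))
    if (!is.null(payload@histogram)) {
      addSeries(doc, "radius", payload@histogram$radius, unit = "nm")
      addSeries(doc, "intensity", payload@histogram$intensity)
    }
  } else if (is(payload, "YieldResult")) {
    xml2::xml_add_child(doc, "yield",
      visual_score = fmtNum(payload@visualScore),
      mass_mg = fmtNum(payload@massMg),
      culture_l = fmtNum(payload@cultureL))
  } else if (is(payload, "LpResult")) {
    lp <- xml2::xml_add_child(doc, "lp")
    for (i in seq_len(nrow(payload@perProtease)))
      xml2::xml_add_child(lp, "protease",
        name = payload@perProtease$protease[i],
        score = as.character(payload@perProtease$score[i]))
  } else if (is(payload, "SequenceRecord")) {
    sq <- xml2::xml_add_child(doc, "sequence", id = payload@id,
      disorder_source = payload@disorderSource)
    xml2::xml_text(sq) <- payload@residues
    if (!is.null(payload@disorderCalls)) {
      calls <- xml2::xml_add_child(doc, "disorder_calls")
      xml2::xml_text(calls) <- paste(as.integer(payload@disorderCalls),
                                     collapse = " ")
    }
  } else {
    stop("no XML serialization for payloads of class ", class(payload)[1])
  }
}

numAttr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v) || v == "NA") NA_real_ else as.numeric(v)
}

#' Read standardized XML back into an experiment summary
#'
#' Inverse of [writeStandardXml()].  Schema violations (unknown experiment
#' tag, summary value outside the tag's schema) are rejected naming the
#' offending element.
#'
#' @param path XML file.
#' @return an [ExperimentSummary-class] with payload reconstructed when
#'   present.
#' @export
readStandardXml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "protchar_result")
    stop("not a standardized result document (root element '",
         xml2::xml_name(doc), "')")
  tag <- xml2::xml_attr(doc, "type")
  if (is.na(tag) || !tag %in% EXPERIMENT_TAGS)
    stop(sprintf("schema error at <protchar_result>: unknown type '%s'", tag))
  prov <- xml2::xml_text(
    xml2::xml_find_first(doc, ".//metadata/meta[@name='provenance']"))
  if (is.na(prov) || !prov %in% c("parsed", "manual")) prov <- "manual"
  valueNodes <- xml2::xml_find_all(doc, ".//analysis/value")
  nms <- xml2::xml_attr(valueNodes, "name")
  schema <- summarySchema(tag)
  bad <- setdiff(nms, schema)
  if (length(bad))
    stop(sprintf("schema error at <value name='%s'>: not allowed for '%s'",
                 bad[1], tag))
  sv <- setNames(as.numeric(xml2::xml_text(valueNodes)), nms)
  payload <- readPayloadXml(doc, tag)
  experimentSummary(tag, sv, provenance = prov, payload = payload)
}

readPayloadXml <- function(doc, tag) {
  if (tag == "dsf") {
    fit <- xml2::xml_find_first(doc, ".//fit")
    if (inherits(fit, "xml_missing")) return(NULL)
    trn <- xml2::xml_find_all(fit, ".//transition")
    tab <- data.frame(tm = vapply(trn, numAttr, numeric(1), "tm"),
                      s = vapply(trn, numAttr, numeric(1), "s"),
                      delta_f = vapply(trn, numAttr, numeric(1), "delta_f"))
    tab$max_slope <- tab$delta_f / (4 * tab$s)
    tab$fwhm <- FWHM_FACTOR * tab$s
    temp <- readSeries(doc, "temperature")
    curve <- NULL
    if (!is.null(temp)) {
      well <- xml2::xml_text(
        xml2::xml_find_first(doc, ".//metadata/meta[@name='well']"))
      curve <- new("DsfCurve", wellLabel = if (is.na(well)) "A1" else well,
                   temperature = temp,
                   fluorescence = readSeries(doc, "fluorescence"))
    }
    new("DsfFit", baseline = numAttr(fit, "baseline"), transitions = tab,
        majorIndex = as.integer(xml2::xml_attr(fit, "major_index")),
        f30 = numAttr(fit, "f30"), fTm = numAttr(fit, "f_tm"),
        rDsf = numAttr(fit, "r_dsf"),
        fitRegion = as.integer(c(xml2::xml_attr(fit, "region_first"),
                                 xml2::xml_attr(fit, "region_last"))),
        rss = numAttr(fit, "rss"), curve = curve, converged = TRUE)
  } else if (tag == "sec") {
    fit <- xml2::xml_find_first(doc, ".//fit")
    if (inherits(fit, "xml_missing")) return(NULL)
    cmp <- xml2::xml_find_all(fit, ".//component")
    comp <- data.frame(height = vapply(cmp, numAttr, numeric(1), "height"),
                       center = vapply(cmp, numAttr, numeric(1), "center"),
                       width = vapply(cmp, numAttr, numeric(1), "width"))
    new("SecFit", components = comp,
        poolRange = c(numAttr(fit, "pool_first"), numAttr(fit, "pool_last")),
        purityPool = numAttr(fit, "purity_pool"),
        rSec = numAttr(fit, "r_sec"), rss = numAttr(fit, "rss"))
  } else if (tag == "dls") {
    pk <- xml2::xml_find_first(doc, ".//peaks")
    if (inherits(pk, "xml_missing")) return(NULL)
    rows <- xml2::xml_find_all(pk, ".//peak")
    peaks <- data.frame(
      rh = vapply(rows, numAttr, numeric(1), "rh"),
      pd = vapply(rows, numAttr, numeric(1), "pd"),
      pd_pct = vapply(rows, numAttr, numeric(1), "pd_pct"),
      intensity_pct = vapply(rows, numAttr, numeric(1), "intensity_pct"),
      mass_pct = vapply(rows, numAttr, numeric(1), "mass_pct"))
    peaks$mw_r <- mwFromRadius(peaks$rh)
    hist <- NULL
    rad <- readSeries(doc, "radius")
    if (!is.null(rad))
      hist <- data.frame(radius = rad, intensity = readSeries(doc, "intensity"))
    new("DlsResult", peaks = peaks, histogram = hist,
        majorIndex = as.integer(xml2::xml_attr(pk, "major_index")),
        majorFallback = as.logical(xml2::xml_attr(pk, "major_fallback")),
        nOlig = numAttr(pk, "n_olig"), pMaj = numAttr(pk, "p_maj"),
        dlsScore = as.integer(xml2::xml_attr(pk, "dls_score")))
  } else if (tag == "yield") {
    y <- xml2::xml_find_first(doc, ".//yield")
    if (inherits(y, "xml_missing")) return(NULL)
    yieldResult(visualScore = numAttr(y, "visual_score"),
                massMg = numAttr(y, "mass_mg"),
                cultureL = numAttr(y, "culture_l"))
  } else if (tag == "lp") {
    lp <- xml2::xml_find_first(doc, ".//lp")
    if (inherits(lp, "xml_missing")) return(NULL)
    rows <- xml2::xml_find_all(lp, ".//protease")
    lpStability(as.integer(xml2::xml_attr(rows, "score")),
                proteases = xml2::xml_attr(rows, "name"))
  } else if (tag == "seq") {
    sq <- xml2::xml_find_first(doc, ".//sequence")
    if (inherits(sq, "xml_missing")) return(NULL)
    callsNode <- xml2::xml_find_first(doc, ".//disorder_calls")
    calls <- NULL
    if (!inherits(callsNode, "xml_missing"))
      calls <- as.logical(as.integer(
        strsplit(trimws(xml2::xml_text(callsNode)), "\\s+")[[1]]))
    rec <- sequenceRecord(xml2::xml_text(sq), id = xml2::xml_attr(sq, "id"),
                          disorderCalls = calls)
    src <- xml2::xml_attr(sq, "disorder_source")
    if (!is.na(src)) rec@disorderSource <- src
    rec
  } else NULL
}
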