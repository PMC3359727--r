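# Generics.  Accessor implementations live next to their classes.

#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @export
setGeneric("rDsf", function(x) standardGeneric("rDsf"))

#' @export
setGeneric("majorIndex", function(x) standardGeneric("majorIndex"))

#' @export
setGeneric("majorIndex<-", function(x, value) standardGeneric("majorIndex<-"))

#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @export
setGeneric("rSec", function(x) standardGeneric("rSec"))

#' @export
setGeneric("purityPool", function(x) standardGeneric("purityPool"))

#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @export
setGeneric("pMajor", function(x) standardGeneric("pMajor"))

#' @export
setGeneric("oligomerRatio", function(x) standardGeneric("oligomerRatio"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @export
setGeneric("typeTag", function(x) standardGeneric("typeTag"))

#' @export
setGeneric("summaryValues", function(x) standardGeneric("summaryValues"))

#' @export
setGeneric("meanScore", function(x) standardGeneric("meanScore"))

#' @export
setGeneric("predictionPath", function(x) standardGeneric("predictionPath"))

#' @export
setGeneric("addResult", function(sample, result, select = TRUE)
  standardGeneric("addResult"))

#' @export
setGeneric("selectResults", function(sample, tag, indices)
  standardGeneric("selectResults"))

#' @export
setGeneric("assembleFeatureVector", function(sample, ...)
  standardGeneric("assembleFeatureVector"))

#' @export
setGeneric("predictOutcome", function(tree, fv, ...)
  standardGeneric("predictOutcome"))
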