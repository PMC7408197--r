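#' @rdname intensities
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setGeneric("sampleData", function(object) standardGeneric("sampleData"))

#' @rdname intensities
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname logRatios
#' @export
setGeneric("logRatios", function(object) standardGeneric("logRatios"))

#' @rdname logRatios
#' @export
setGeneric("transformTag", function(object) standardGeneric("transformTag"))

#' @rdname closeComposition
#' @export
setGeneric("closeComposition",
           function(object, ...) standardGeneric("closeComposition"))

#' @rdname clr
#' @export
setGeneric("clr", function(object, ...) standardGeneric("clr"))

#' @rdname clr
#' @export
setGeneric("ilr", function(object, ...) standardGeneric("ilr"))

#' @rdname cpcScores
#' @export
setGeneric("cpcScores", function(object) standardGeneric("cpcScores"))

#' @rdname cpcScores
#' @export
setGeneric("cpcLoadings", function(object) standardGeneric("cpcLoadings"))

#' @rdname cpcScores
#' @export
setGeneric("varianceFractions",
           function(object, all = FALSE) standardGeneric("varianceFractions"))

#' @rdname cpcScores
#' @export
setGeneric("retainedComponents",
           function(object) standardGeneric("retainedComponents"))

#' @rdname importanceScores
#' @export
setGeneric("importanceScores",
           function(object, ...) standardGeneric("importanceScores"))

#' @rdname looPredictions
#' @export
setGeneric("looPredictions",
           function(object) standardGeneric("looPredictions"))

#' @rdname looPredictions
#' @export
setGeneric("classMetrics", function(object) standardGeneric("classMetrics"))

#' @rdname looPredictions
#' @export
setGeneric("confusionMatrix",
           function(object) standardGeneric("confusionMatrix"))
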