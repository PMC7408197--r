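#' Accessors for IntensityMatrix
#'
#' `intensities()` returns the raw signal matrix (transitions x samples),
#' `sampleData()` the per-sample metadata as a `DataFrame`, and
#' `transitions()` the [TransitionTable-class] annotation.
#'
#' @param object an [IntensityMatrix-class].
#' @return A matrix, `DataFrame` or `TransitionTable` respectively.
#' @name intensities
#' @aliases sampleData transitions
NULL

#' @rdname intensities
#' @export
setMethod("intensities", "IntensityMatrix",
          function(object) assay(object, "intensity"))

#' @rdname intensities
#' @export
setMethod("sampleData", "SummarizedExperiment",
          function(object) colData(object))

#' @rdname intensities
#' @export
setMethod("transitions", "IntensityMatrix", function(object) {
  df <- rowData(object)
  new("TransitionTable", as(df, "DFrame"))
})

setMethod("show", "IntensityMatrix", function(object) {
  cat("IntensityMatrix:", nrow(object), "transitions x",
      ncol(object), "samples\n")
  cd <- colData(object)
  cat("  genotype:", paste(names(table(cd$genotype)),
                           table(cd$genotype), collapse = ", "), "\n")
  cat("  stages:  ", paste(names(table(cd$stage)),
                           table(cd$stage), collapse = ", "), "\n")
  cat("  categories:", length(unique(rowData(object)$category)), "\n")
})

#' Accessors for LogRatioMatrix
#'
#' `logRatios()` returns the transformed matrix (features x samples);
#' `transformTag()` returns `"clr"` or `"ilr"`.
#'
#' @param object a [LogRatioMatrix-class].
#' @name logRatios
NULL

#' @rdname logRatios
#' @export
setMethod("logRatios", "LogRatioMatrix",
          function(object) assay(object, "logratio"))

#' @rdname logRatios
#' @export
setMethod("transformTag", "LogRatioMatrix",
          function(object) metadata(object)$transform)

setMethod("show", "LogRatioMatrix", function(object) {
  cat("LogRatioMatrix (", metadata(object)$transform, "): ",
      nrow(object), " features x ", ncol(object), " samples\n", sep = "")
})

#' Accessors for CompressedFeatureSet
#'
#' `cpcScores()` returns the samples x k score matrix, `cpcLoadings()` the
#' k x features loading matrix, `varianceFractions()` the per-component
#' variance fractions (`all = TRUE` includes discarded components), and
#' `retainedComponents()` the retained component count k.
#'
#' @param object a [CompressedFeatureSet-class].
#' @param all logical; return variance fractions of all components?
#' @name cpcScores
NULL

#' @rdname cpcScores
#' @export
setMethod("cpcScores", "CompressedFeatureSet", function(object) object@scores)

#' @rdname cpcScores
#' @export
setMethod("cpcLoadings", "CompressedFeatureSet",
          function(object) object@loadings)

#' @rdname cpcScores
#' @export
setMethod("varianceFractions", "CompressedFeatureSet",
          function(object, all = FALSE) {
  if (all) object@allVarianceFraction else object@varianceFraction
})

#' @rdname cpcScores
#' @export
setMethod("retainedComponents", "CompressedFeatureSet",
          function(object) object@k)

setMethod("show", "CompressedFeatureSet", function(object) {
  cat("CompressedFeatureSet [", object@category, "]: ",
      ncol(object@loadings), " features -> ", object@k,
      " CPCs (", round(100 * sum(object@varianceFraction), 1),
      "% variance)\n", sep = "")
})

#' Accessors for EnetResult
#'
#' `looPredictions()` returns per-sample leave-one-out predictions and class
#' probabilities, `classMetrics()` the metric list (accuracy, exact binomial
#' CI, unweighted/weighted Cohen's kappa), and `confusionMatrix()` the
#' class x class LOO contingency table.
#'
#' @param object an [EnetResult-class].
#' @name looPredictions
NULL

#' @rdname looPredictions
#' @export
setMethod("looPredictions", "EnetResult",
          function(object) object@looPredictions)

#' @rdname looPredictions
#' @export
setMethod("classMetrics", "EnetResult", function(object) object@metrics)

#' @rdname looPredictions
#' @export
setMethod("confusionMatrix", "EnetResult", function(object) object@confusion)

setMethod("show", "EnetResult", function(object) {
  m <- object@metrics
  cat("EnetResult (", object@family, "): ",
      nrow(object@coefficients), " features, alpha = ", object@alpha,
      ", lambda = ", signif(object@lambda, 3), "\n", sep = "")
  if (!is.null(m$accuracy)) {
    cat(sprintf("  LOO accuracy %.3f (95%% CI %.3f-%.3f)\n",
                m$accuracy, m$accuracy_ci[1], m$accuracy_ci[2]))
    if (!is.null(m$kappa_unweighted)) {
      cat(sprintf("  kappa %.3f (unweighted), %.3f (weighted)\n",
                  m$kappa_unweighted, m$kappa_weighted))
    }
  }
})
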