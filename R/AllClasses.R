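#' TransitionTable: annotated MRM transitions
#'
#' A table of monitored MRM transitions (precursor/product ion pairs) with
#' their polarity, collision energy, tentative lipid attribution and lipid
#' category.  Extends [S4Vectors::DataFrame] and enforces the invariants of
#' the monitoring method: positive m/z values, product m/z not exceeding the
#' precursor by more than 2 Th (near-equal precursor scans are allowed), a
#' closed set of category labels, and no duplicated
#' (precursor, product, polarity) triple.
#'
#' @slot rownames,nrows,elementType,elementMetadata,metadata,listData
#'   inherited from [S4Vectors::DataFrame].
#' @seealso [readMethodTable()] to construct one from a CSV method table.
#' @export
setClass("TransitionTable", contains = "DFrame")

.required_transition_cols <- c(
  "transition_id", "precursor_mz", "product_mz", "polarity", "category"
)

.validTransitionTable <- function(object) {
  msg <- character()
  missing <- setdiff(.required_transition_cols, colnames(object))
  if (length(missing)) {
    return(paste("missing required column(s):", paste(missing, collapse = ", ")))
  }
  q1 <- object$precursor_mz
  q3 <- object$product_mz
  if (!is.numeric(q1) || !is.numeric(q3)) {
    msg <- c(msg, "precursor_mz and product_mz must be numeric")
  } else {
    if (any(q1 <= 0) || any(q3 <= 0)) {
      msg <- c(msg, "all m/z values must be positive")
    }
    if (any(q3 > q1 + 2.0)) {
      msg <- c(msg, "product_mz must not exceed precursor_mz + 2.0 Th")
    }
  }
  if (!all(object$polarity %in% c("positive", "negative"))) {
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  }
  bad <- setdiff(object$category, LIPID_CATEGORIES)
  if (length(bad)) {
    msg <- c(msg, paste0(
      "unknown category label(s): ", paste(unique(bad), collapse = ", ")
    ))
  }
  if (anyDuplicated(object$transition_id)) {
    msg <- c(msg, "transition_id values must be unique")
  }
  key <- paste(q1, q3, object$polarity)
  if (anyDuplicated(key)) {
    msg <- c(msg, "duplicated (precursor_mz, product_mz, polarity) triple")
  }
  if (length(msg)) msg else TRUE
}

setValidity("TransitionTable", .validTransitionTable)

#' Construct a TransitionTable
#'
#' @param transition_id character, unique identifiers (default:
#'   `"Q1->Q3"` strings built from the m/z values).
#' @param precursor_mz,product_mz numeric m/z values (Th).
#' @param polarity `"positive"` or `"negative"`, recycled.
#' @param collision_energy collision energy in volts, recycled.
#' @param attribution free-text tentative lipid attribution(s).
#' @param category lipid category label, one of [lipidCategories()].
#' @return A [TransitionTable-class] object.
#' @examples
#' TransitionTable(
#'   precursor_mz = c(800.6, 666.4), product_mz = c(184.1, 264.3),
#'   polarity = "positive", category = c("phospholipid", "sphingolipid")
#' )
#' @export
TransitionTable <- function(transition_id = NULL, precursor_mz, product_mz,
                            polarity = "positive", collision_energy = NA_real_,
                            attribution = NA_character_, category) {
  n <- length(precursor_mz)
  if (is.null(transition_id)) {
    transition_id <- sprintf("%s->%s", precursor_mz, product_mz)
  }
  df <- DataFrame(
    transition_id = as.character(transition_id),
    precursor_mz = as.numeric(precursor_mz),
    product_mz = as.numeric(product_mz),
    polarity = rep_len(as.character(polarity), n),
    collision_energy = rep_len(as.numeric(collision_energy), n),
    attribution = rep_len(as.character(attribution), n),
    category = as.character(category)
  )
  rownames(df) <- df$transition_id
  new("TransitionTable", df)
}

#' IntensityMatrix: samples-by-transitions MRM signal
#'
#' Raw (or merged) flow-injection MRM signal intensities, stored as a
#' [SummarizedExperiment::SummarizedExperiment] with one assay
#' (`"intensity"`), rows = transitions (with the [TransitionTable-class]
#' annotation as `rowData`) and columns = samples (with `sex`, `genotype`,
#' `age_weeks` and `stage` as `colData`).  All values are nonnegative and the
#' stage label is `"control"` exactly for wild-type samples.
#'
#' @seealso [IntensityMatrix()], [extractIntensities()],
#'   [simulateLipidomics()].
#' @export
setClass("IntensityMatrix", contains = "SummarizedExperiment")

.validIntensityMatrix <- function(object) {
  msg <- character()
  if (!"intensity" %in% names(assays(object))) {
    return("assay 'intensity' is required")
  }
  v <- assay(object, "intensity")
  if (any(!is.finite(v))) msg <- c(msg, "intensities must be finite")
  else if (any(v < 0)) msg <- c(msg, "intensities must be nonnegative")
  cd <- colData(object)
  need <- c("sex", "genotype", "age_weeks", "stage")
  missing <- setdiff(need, colnames(cd))
  if (length(missing)) {
    return(paste("missing sample metadata column(s):",
                 paste(missing, collapse = ", ")))
  }
  if (!all(cd$sex %in% c("F", "M"))) msg <- c(msg, "sex must be 'F' or 'M'")
  if (!all(cd$genotype %in% c("WT", "cpdm"))) {
    msg <- c(msg, "genotype must be 'WT' or 'cpdm'")
  }
  if (!all(cd$stage %in% STAGE_LEVELS)) {
    msg <- c(msg, paste("stage must be one of:",
                        paste(STAGE_LEVELS, collapse = ", ")))
  } else {
    ctrl <- cd$stage == "control"
    wt <- cd$genotype == "WT"
    if (!identical(as.logical(ctrl), as.logical(wt))) {
      msg <- c(msg, "stage is 'control' iff genotype is 'WT'")
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("IntensityMatrix", .validIntensityMatrix)

#' Construct an IntensityMatrix
#'
#' @param values numeric matrix of nonnegative intensities, transitions in
#'   rows and samples in columns (dimnames used as identifiers).
#' @param transitions a [TransitionTable-class] aligned with `rownames(values)`.
#' @param sampleData a `data.frame` or `DataFrame` with one row per sample and
#'   columns `sex` (`"F"`/`"M"`), `genotype` (`"WT"`/`"cpdm"`), `age_weeks`
#'   and `stage` (see [stageLevels()]).
#' @return An [IntensityMatrix-class] object.
#' @export
IntensityMatrix <- function(values, transitions, sampleData) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- transitions$transition_id
  transitions <- transitions[match(rownames(values),
                                   transitions$transition_id), ]
  sampleData <- as(sampleData, "DataFrame")
  if (is.null(rownames(sampleData)) && !is.null(colnames(values))) {
    rownames(sampleData) <- colnames(values)
  }
  se <- SummarizedExperiment(
    assays = list(intensity = values),
    rowData = transitions,
    colData = sampleData
  )
  new("IntensityMatrix", se)
}

#' LogRatioMatrix: log-ratio transformed compositional data
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding CLR- or
#' ILR-transformed compositions in the `"logratio"` assay (rows = features,
#' columns = samples).  `metadata()` records the transform tag (`"clr"` or
#' `"ilr"`), the number of compositional parts, and — for ILR — the
#' orthonormal contrast basis used.  CLR columns sum to zero; ILR has
#' `parts - 1` rows.
#'
#' @seealso [clr()], [ilr()], [transformTag()].
#' @export
setClass("LogRatioMatrix", contains = "SummarizedExperiment")

.validLogRatioMatrix <- function(object) {
  tag <- metadata(object)$transform
  if (is.null(tag) || !tag %in% c("clr", "ilr")) {
    return("metadata(object)$transform must be 'clr' or 'ilr'")
  }
  if (!"logratio" %in% names(assays(object))) {
    return("assay 'logratio' is required")
  }
  v <- assay(object, "logratio")
  if (tag == "clr") {
    cs <- colSums(v)
    if (any(abs(cs) > 1e-9 * pmax(1, colSums(abs(v))))) {
      return("clr columns must sum to 0 (within 1e-9)")
    }
  } else {
    parts <- metadata(object)$n_parts
    if (is.null(parts) || nrow(v) != parts - 1L) {
      return("ilr must have n_parts - 1 coordinates")
    }
  }
  TRUE
}

setValidity("LogRatioMatrix", .validLogRatioMatrix)

#' CompressedFeatureSet: per-category CPC compression
#'
#' The result of SVD-based compression of (one lipid category of) a
#' log-ratio matrix: retained compositional principal component scores,
#' orthonormal loadings, and the variance fraction carried by every
#' component (retained and discarded, so the full vector sums to 1).
#'
#' @slot category category label, or `"global"` for a whole-matrix fit.
#' @slot scores numeric matrix, samples x k retained component scores.
#' @slot loadings numeric matrix, k x features; rows are orthonormal right
#'   singular vectors under a deterministic sign convention.
#' @slot varianceFraction numeric, variance fraction of each retained
#'   component (nonincreasing).
#' @slot allVarianceFraction numeric, variance fractions of all components;
#'   sums to 1.
#' @slot k integer, number of retained components.
#' @slot transform the log-ratio transform tag of the input.
#' @seealso [fitCPC()], [compressCategories()], [variableContributions()].
#' @export
setClass("CompressedFeatureSet",
  representation(
    category = "character",
    scores = "matrix",
    loadings = "matrix",
    varianceFraction = "numeric",
    allVarianceFraction = "numeric",
    k = "integer",
    transform = "character"
  )
)

.validCompressedFeatureSet <- function(object) {
  msg <- character()
  k <- object@k
  if (ncol(object@scores) != k || nrow(object@loadings) != k ||
      length(object@varianceFraction) != k) {
    msg <- c(msg, "scores, loadings and varianceFraction must agree with k")
  }
  vf <- object@varianceFraction
  if (k > 1 && any(diff(vf) > 1e-12)) {
    msg <- c(msg, "variance fractions must be nonincreasing")
  }
  if (abs(sum(object@allVarianceFraction) - 1) > 1e-9) {
    msg <- c(msg, "variance fractions over all components must sum to 1")
  }
  G <- tcrossprod(object@loadings)
  if (max(abs(G - diag(k))) > 1e-8) {
    msg <- c(msg, "loading rows must be orthonormal (within 1e-8)")
  }
  if (length(msg)) msg else TRUE
}

setValidity("CompressedFeatureSet", .validCompressedFeatureSet)

#' EnetResult: fitted elastic-net classifier with LOO evaluation
#'
#' Holds the elastic-net fit at the selected penalty, per-class coefficients
#' on the standardized predictor scale, leave-one-out class predictions and
#' probabilities, |beta|-based importance scores, the confusion matrix and
#' classification metrics (accuracy with exact binomial CI, unweighted and
#' weighted Cohen's kappa).
#'
#' @slot coefficients numeric matrix, features x classes (one column for a
#'   binomial fit); standardized scale when inputs were standardized.
#' @slot intercepts numeric, per-class intercepts.
#' @slot alpha,lambda selected elastic-net mixing and penalty parameters.
#' @slot family `"binomial"` or `"multinomial"` (or `"gaussian"` in
#'   regression check mode).
#' @slot looPredictions `DataFrame` with observed and predicted class per
#'   sample plus one probability column per class.
#' @slot importance `DataFrame` of per-class and overall importance scores.
#' @slot confusion class x class contingency table of LOO predictions.
#' @slot metrics list: `accuracy`, `accuracy_ci`, `kappa_unweighted`,
#'   `kappa_weighted`.
#' @slot config the [enetConfig()] list used for training.
#' @seealso [trainEnet()], [importanceScores()], [classificationMetrics()].
#' @export
setClass("EnetResult",
  representation(
    coefficients = "matrix",
    intercepts = "numeric",
    alpha = "numeric",
    lambda = "numeric",
    family = "character",
    looPredictions = "DFrame",
    importance = "DFrame",
    confusion = "matrix",
    metrics = "list",
    config = "list"
  )
)
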