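## SVD-driven compositional principal components and per-category
## compression into CPC feature sets.

#' Fit compositional principal components by SVD
#'
#' Column-centers a log-ratio matrix (samples x features) and computes its
#' singular value decomposition.  Scores are the centered data projected on
#' the right singular vectors; the variance fraction of component `i` is
#' `sigma_i^2 / sum(sigma^2)`.  A deterministic sign convention is applied:
#' the largest-magnitude loading of each component is positive, so CPC
#' features are reproducible across runs and platforms.
#'
#' @param x numeric matrix of log-ratio values, samples in rows, or a
#'   [LogRatioMatrix-class].
#' @param nComponents either an integer number of components to retain, or a
#'   variance target in (0, 1]: the smallest component count whose cumulative
#'   variance fraction reaches the target is kept.  Default 0.95.
#' @param category label stored in the result (default `"global"`).
#' @return A [CompressedFeatureSet-class].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 10, 6)
#' fitCPC(x, nComponents = 2)
#' @export
fitCPC <- function(x, nComponents = 0.95, category = "global") {
  if (is(x, "LogRatioMatrix")) x <- t(assay(x, "logratio"))
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 samples and 2 features")
  }
  xc <- sweep(x, 2, colMeans(x), "-")
  s <- svd(xc)
  ev <- s$d^2
  tot <- sum(ev)
  if (tot <= .Machine$double.eps * length(ev)) {
    stop("degenerate input: matrix is constant (rank 0 after centering)")
  }
  vf_all <- ev / tot
  r <- min(nrow(x) - 1L, ncol(x))   # max meaningful rank after centering
  if (length(nComponents) != 1L || nComponents <= 0) {
    stop("nComponents must be a positive scalar")
  }
  if (nComponents <= 1) {
    ## variance target: smallest k with cumulative variance >= target
    k <- which(cumsum(vf_all) >= nComponents - 1e-12)[1]
    if (is.na(k)) k <- r
    k <- min(as.integer(k), r)
  } else {
    k <- min(as.integer(nComponents), r)
  }
  loadings <- t(s$v[, seq_len(k), drop = FALSE])
  scores <- xc %*% t(loadings)
  ## sign convention: largest-|loading| entry of each component is positive
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  fn <- sprintf("%s CPC %d", category, seq_len(k))
  dimnames(scores) <- list(rownames(x), fn)
  dimnames(loadings) <- list(fn, colnames(x))
  new("CompressedFeatureSet",
      category = category,
      scores = scores,
      loadings = loadings,
      varianceFraction = vf_all[seq_len(k)],
      allVarianceFraction = vf_all,
      k = k,
      transform = "clr")
}

#' Compress each lipid category into CPC features
#'
#' Treats each lipid category as its own composition: the category's
#' transitions are subset from the raw intensity matrix, re-closed,
#' zero-replaced, CLR-transformed and compressed with [fitCPC()], keeping the
#' smallest component count that retains `varianceTarget` of the category
#' variance.  The per-category scores are column-bound into a combined
#' feature matrix with names like `"sphingolipid CPC 4"`.
#'
#' Categories with fewer than 2 transitions cannot form a composition and
#' are skipped with a warning.
#'
#' @param object an [IntensityMatrix-class] with category annotation in its
#'   transition table.
#' @param varianceTarget per-category retained variance fraction
#'   (default 0.95).
#' @param deltaFraction zero-replacement delta fraction, see [replaceZeros()].
#' @param globalClr if `TRUE`, slice a whole-matrix CLR instead of re-closing
#'   each category subcomposition (non-default alternative; reported in the
#'   result).
#' @return A list with elements `sets` (named list of
#'   [CompressedFeatureSet-class], one per usable category), `features`
#'   (samples x total-CPC combined matrix) and `mode`
#'   (`"subcomposition"` or `"global-clr"`).
#' @export
compressCategories <- function(object, varianceTarget = 0.95,
                               deltaFraction = 0.65, globalClr = FALSE) {
  stopifnot(is(object, "IntensityMatrix"))
  cats <- rowData(object)$category
  raw <- t(assay(object, "intensity"))   # samples x transitions
  global_lr <- NULL
  if (globalClr) {
    comp <- replaceZeros(closeComposition(raw), deltaFraction = deltaFraction)
    global_lr <- clr(comp)
  }
  sets <- list()
  for (cat_label in unique(cats)) {
    idx <- which(cats == cat_label)
    if (length(idx) < 2L) {
      warning("category '", cat_label, "' has < 2 transitions; skipped")
      next
    }
    lr <- if (globalClr) {
      global_lr[, idx, drop = FALSE]
    } else {
      sub <- raw[, idx, drop = FALSE]
      comp <- replaceZeros(closeComposition(sub),
                           deltaFraction = deltaFraction)
      clr(comp)
    }
    sets[[cat_label]] <- fitCPC(lr, nComponents = varianceTarget,
                                category = cat_label)
  }
  if (!length(sets)) stop("no category with >= 2 transitions")
  features <- do.call(cbind, lapply(sets, cpcScores))
  list(sets = sets, features = features,
       mode = if (globalClr) "global-clr" else "subcomposition")
}

#' Per-feature contribution to a component
#'
#' The percent contribution of each feature to one retained component:
#' `100 * loading_i^2 / sum(loadings^2)`; contributions sum to 100.
#'
#' @param cfs a [CompressedFeatureSet-class].
#' @param component component index (<= `retainedComponents(cfs)`).
#' @return A named numeric vector of percent contributions.
#' @export
variableContributions <- function(cfs, component = 1L) {
  stopifnot(is(cfs, "CompressedFeatureSet"))
  if (component < 1L || component > cfs@k) {
    stop("component must be between 1 and ", cfs@k)
  }
  l <- cfs@loadings[component, ]
  100 * l^2 / sum(l^2)
}
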