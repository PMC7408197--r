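## Compositional preprocessing: closure, zero replacement, CLR/ILR, and
## reference-group standardization.  Plain-matrix methods use the
## compositional convention rows = samples, columns = parts; the
## IntensityMatrix / LogRatioMatrix methods wrap them, keeping the
## SummarizedExperiment orientation (features x samples).

#' Close a matrix of relative amounts to unit-sum compositions
#'
#' Divides each sample by its total signal so rows carry only relative
#' information (total-ion-count normalization).  Zeros are preserved.
#'
#' @param object a numeric matrix with samples in rows, or an
#'   [IntensityMatrix-class].
#' @param ... unused.
#' @return For a matrix, a matrix whose rows sum to 1; for an
#'   `IntensityMatrix`, an `IntensityMatrix` whose columns sum to 1.
#' @examples
#' closeComposition(matrix(c(2, 2, 4), 1, 3))
#' @export
setMethod("closeComposition", "matrix", function(object, ...) {
  if (any(object < 0)) stop("negative values are not compositional")
  tot <- rowSums(object)
  bad <- which(tot <= 0)
  if (length(bad)) {
    stop("degenerate sample(s) with zero total signal: ",
         paste(if (is.null(rownames(object))) bad else
               rownames(object)[bad], collapse = ", "))
  }
  object / tot
})

#' @rdname closeComposition
#' @export
setMethod("closeComposition", "IntensityMatrix", function(object, ...) {
  closed <- t(closeComposition(t(assay(object, "intensity"))))
  out <- object
  assays(out)$intensity <- closed
  out
})

#' Replace zeros in a closed composition
#'
#' Log-ratios are undefined at zero.  The multiplicative strategy replaces
#' each zero with `delta = deltaFraction *` (smallest positive value observed
#' for that part across samples) and rescales the nonzero parts of the row so
#' it still sums to 1.  The pseudocount strategy adds a constant to every
#' cell and re-closes.  Parts that are zero in every sample cannot be
#' imputed and are dropped with a warning.
#'
#' @param composition numeric matrix of closed compositions (rows = samples,
#'   rows sum to 1).
#' @param strategy `"multiplicative"` (default) or `"pseudocount"`.
#' @param deltaFraction fraction of the column minimum used as the imputed
#'   value (multiplicative strategy); default 0.65.
#' @param pseudocount constant added before re-closure (pseudocount
#'   strategy); default the smallest positive value in the matrix times
#'   `deltaFraction`.
#' @return A strictly positive matrix with rows summing to 1 (possibly with
#'   fewer columns if all-zero parts were dropped).
#' @examples
#' x <- closeComposition(matrix(c(5, 5, 0, 4, 4, 2), 2, 3, byrow = TRUE))
#' replaceZeros(x)
#' @export
replaceZeros <- function(composition, strategy = c("multiplicative",
                                                   "pseudocount"),
                         deltaFraction = 0.65, pseudocount = NULL) {
  strategy <- match.arg(strategy)
  x <- as.matrix(composition)
  if (any(x < 0)) stop("composition must be nonnegative")
  allzero <- colSums(x > 0) == 0
  if (any(allzero)) {
    warning("dropping ", sum(allzero), " part(s) that are zero in every ",
            "sample: ", paste(colnames(x)[allzero], collapse = ", "))
    x <- x[, !allzero, drop = FALSE]
    x <- x / rowSums(x)
  }
  if (!any(x == 0)) return(x)
  if (strategy == "multiplicative") {
    colmin <- apply(x, 2, function(v) min(v[v > 0]))
    delta <- deltaFraction * colmin
    out <- x
    for (i in seq_len(nrow(x))) {
      z <- x[i, ] == 0
      if (!any(z)) next
      dsum <- sum(delta[z])
      if (dsum >= 1) stop("imputed zeros exceed the unit total in sample ",
                          i, "; lower deltaFraction")
      out[i, z] <- delta[z]
      out[i, !z] <- x[i, !z] * (1 - dsum)
    }
    out
  } else {
    if (is.null(pseudocount)) {
      pseudocount <- deltaFraction * min(x[x > 0])
    }
    y <- x + pseudocount
    y / rowSums(y)
  }
}

.geometric_center <- function(x) exp(rowMeans(log(x)))

#' Centered log-ratio transform
#'
#' Maps each strictly positive composition row to
#' `log(x_i / g(x))` where `g(x)` is the row geometric mean.  Output rows sum
#' to zero and are invariant to rescaling of the raw sample.
#'
#' @param object a strictly positive matrix with samples in rows, or an
#'   [IntensityMatrix-class] (which is closed, zero-replaced, then
#'   transformed).
#' @param ... passed to [replaceZeros()] for the `IntensityMatrix` method.
#' @return For a matrix, a matrix of CLR coordinates; for an
#'   `IntensityMatrix`, a [LogRatioMatrix-class].
#' @examples
#' clr(matrix(c(0.8, 0.2), 1, 2))
#' @export
setMethod("clr", "matrix", function(object, ...) {
  if (any(object <= 0)) stop("clr requires strictly positive compositions")
  lx <- log(object)
  lx - rowMeans(lx)
})

#' @rdname clr
#' @export
setMethod("clr", "IntensityMatrix", function(object, ...) {
  comp <- closeComposition(t(assay(object, "intensity")))
  comp <- replaceZeros(comp, ...)
  v <- clr(comp)
  se <- SummarizedExperiment(
    assays = list(logratio = t(v)),
    colData = colData(object)
  )
  metadata(se)$transform <- "clr"
  metadata(se)$n_parts <- ncol(comp)
  new("LogRatioMatrix", se)
})

#' Orthonormal pivot (sequential binary partition) ILR basis
#'
#' Returns the `(D-1) x D` contrast matrix of pivot coordinates: coordinate
#' `i` balances part `i` against the geometric mean of parts `i+1, ..., D`.
#' Rows are orthonormal and orthogonal to the all-ones vector, so the basis
#' spans the CLR plane.
#'
#' @param D number of compositional parts (>= 2).
#' @return A `(D-1) x D` numeric matrix.
#' @export
ilrBasis <- function(D) {
  stopifnot(D >= 2)
  V <- matrix(0, D - 1L, D)
  for (i in seq_len(D - 1L)) {
    r <- D - i
    V[i, i] <- sqrt(r / (r + 1))
    V[i, (i + 1L):D] <- -sqrt(r / (r + 1)) / r
  }
  V
}

#' Isometric log-ratio transform
#'
#' Projects CLR coordinates on an orthonormal sequential-binary-partition
#' contrast basis, giving `D - 1` unconstrained coordinates per sample with
#' the same Euclidean geometry as CLR (`||ilr(x)|| == ||clr(x)||`).
#'
#' @param object a strictly positive matrix with samples in rows, or an
#'   [IntensityMatrix-class].
#' @param basis optional `(D-1) x D` orthonormal contrast matrix; default the
#'   pivot basis of [ilrBasis()].
#' @param ... passed to [replaceZeros()] for the `IntensityMatrix` method.
#' @return ILR coordinates (matrix, or [LogRatioMatrix-class] with the basis
#'   recorded in `metadata()`).
#' @examples
#' ilr(matrix(c(0.8, 0.2), 1, 2))  # (1/sqrt(2)) * log(0.8/0.2)
#' @export
setMethod("ilr", "matrix", function(object, basis = NULL, ...) {
  D <- ncol(object)
  if (is.null(basis)) basis <- ilrBasis(D)
  if (!is.matrix(basis) || nrow(basis) != D - 1L || ncol(basis) != D) {
    stop("basis must be a (D-1) x D matrix")
  }
  G <- tcrossprod(basis)
  if (max(abs(G - diag(D - 1L))) > 1e-8 ||
      max(abs(rowSums(basis))) > 1e-8) {
    stop("basis rows must be orthonormal contrasts (sum to zero)")
  }
  clr(object) %*% t(basis)
})

#' @rdname ilr
#' @export
setMethod("ilr", "IntensityMatrix", function(object, basis = NULL, ...) {
  comp <- closeComposition(t(assay(object, "intensity")))
  comp <- replaceZeros(comp, ...)
  if (is.null(basis)) basis <- ilrBasis(ncol(comp))
  v <- ilr(comp, basis = basis)
  colnames(v) <- sprintf("ilr%d", seq_len(ncol(v)))
  se <- SummarizedExperiment(
    assays = list(logratio = t(v)),
    colData = colData(object)
  )
  metadata(se)$transform <- "ilr"
  metadata(se)$n_parts <- ncol(comp)
  metadata(se)$basis <- basis
  new("LogRatioMatrix", se)
})

#' Standardize features to a reference subgroup
#'
#' Centers and scales every feature by the mean and standard deviation of a
#' reference sample subset (e.g. wild-type females), so values read as
#' "standard deviations away from the reference group".  Features constant
#' within the reference are flagged and set to `NA` with a warning.
#'
#' @param features numeric matrix, samples in rows, or a
#'   [LogRatioMatrix-class].
#' @param reference logical or integer index, or character sample ids,
#'   selecting the reference samples.
#' @return A matrix (samples x features) of standardized values with
#'   attribute `"flagged"` naming any zero-variance features.  Standardized
#'   values are no longer compositional log-ratios, so the result is a plain
#'   matrix even for a `LogRatioMatrix` input.
#' @export
standardizeToReference <- function(features, reference) {
  x <- if (is(features, "LogRatioMatrix")) {
    t(assay(features, "logratio"))
  } else {
    as.matrix(features)
  }
  if (is.character(reference)) reference <- rownames(x) %in% reference
  ref <- x[reference, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference subset is empty")
  mu <- colMeans(ref)
  sdev <- apply(ref, 2, sd)
  flagged <- which(sdev == 0 | !is.finite(sdev))
  if (length(flagged)) {
    warning(length(flagged), " feature(s) constant in the reference group; ",
            "set to NA")
    sdev[flagged] <- NA_real_
  }
  out <- sweep(sweep(x, 2, mu, "-"), 2, sdev, "/")
  attr(out, "flagged") <- colnames(x)[flagged]
  out
}
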