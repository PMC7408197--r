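## Tier-1 filter: per-feature linear models against sex, genotype, or
## ordinal disease progression; eta-squared / partial eta-squared effect
## sizes; BH adjustment; inclusion/exclusion selection rules; effect-size
## conversions.

#' Numeric coding of the ordinal disease stages
#'
#' Maps stage labels to the monotone scores control = 0, non-lesional = 1,
#' established = 2, advanced = 3 used when disease progression enters a
#' linear model as a numeric trend.
#'
#' @param stage character vector of stage labels.
#' @return A numeric vector of scores.
#' @export
progressionCoding <- function(stage) {
  scores <- setNames(0:3, STAGE_LEVELS)
  if (!all(stage %in% STAGE_LEVELS)) {
    stop("unknown stage label(s): ",
         paste(setdiff(unique(stage), STAGE_LEVELS), collapse = ", "))
  }
  unname(scores[stage])
}

.factor_predictor <- function(metadata, factor,
                              progression = c("numeric", "categorical")) {
  progression <- match.arg(progression)
  switch(factor,
    sex = base::factor(metadata$sex),
    genotype = base::factor(metadata$genotype),
    progression = {
      if (progression == "numeric") progressionCoding(metadata$stage)
      else base::factor(metadata$stage, levels = STAGE_LEVELS)
    },
    stop("factor must be 'sex', 'genotype' or 'progression'")
  )
}

#' Per-feature linear models with effect sizes
#'
#' Fits one ordinary-least-squares model per feature, with the feature as
#' response and the chosen study factor (optionally preceded by covariates)
#' as predictor.  Disease progression enters as the numeric ordinal score of
#' [progressionCoding()] by default, or as a 4-level factor with
#' `progression = "categorical"`.  Effect sizes come from the sequential
#' sum-of-squares decomposition with the factor entered last:
#' `eta2 = SS_factor / SS_total` and
#' `partial_eta2 = SS_factor / (SS_factor + SS_error)`; with no covariates
#' the two coincide.  P-values are the sequential F tests of the factor
#' term.  Constant features are flagged and reported with `eta2 = 0`,
#' `p = 1`.
#'
#' @param features numeric matrix (samples x features), or a
#'   [LogRatioMatrix-class] (transposed internally).
#' @param metadata per-sample metadata with columns `sex`, `genotype`,
#'   `stage` (a `data.frame` or `DataFrame`); for a `LogRatioMatrix` input
#'   the default is its own `colData`.
#' @param factor `"sex"`, `"genotype"` or `"progression"`.
#' @param covariates optional character vector of additional factors
#'   (from the same three) entered before the factor of interest.
#' @param progression `"numeric"` (ordinal trend, default) or
#'   `"categorical"`.
#' @param adjust if `TRUE` (default) append BH-adjusted p-values over the
#'   family of features tested here.
#' @return A `data.frame` with one row per feature: `feature_id`, `factor`,
#'   `coefficient` (slope/contrast of the factor term; `NA` for a
#'   multi-level factor), `eta2`, `partial_eta2`, `p_value`, `p_adjusted`,
#'   `n`, `flagged`.
#' @export
fitFeatureModels <- function(features, metadata = NULL,
                             factor = c("genotype", "sex", "progression"),
                             covariates = NULL,
                             progression = c("numeric", "categorical"),
                             adjust = TRUE) {
  factor <- match.arg(factor)
  progression <- match.arg(progression)
  if (is(features, "LogRatioMatrix")) {
    if (is.null(metadata)) metadata <- colData(features)
    features <- t(assay(features, "logratio"))
  }
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("feature%d", seq_len(ncol(features)))
  }
  metadata <- as.data.frame(metadata)
  stopifnot(nrow(metadata) == nrow(features))
  pred <- .factor_predictor(metadata, factor, progression)
  if (length(unique(pred)) < 2L) stop("factor has fewer than 2 levels")
  covs <- lapply(covariates, .factor_predictor, metadata = metadata,
                 progression = progression)
  names(covs) <- covariates
  n <- nrow(features)
  res <- if (length(covs) == 0L) {
    .fit_single_predictor(features, pred)
  } else {
    .fit_with_covariates(features, pred, covs)
  }
  out <- data.frame(
    feature_id = colnames(features),
    factor = factor,
    coefficient = res$coefficient,
    eta2 = res$eta2,
    partial_eta2 = res$partial_eta2,
    p_value = res$p_value,
    n = n,
    flagged = res$flagged,
    row.names = NULL
  )
  if (adjust) out$p_adjusted <- bhAdjust(out$p_value)
  out[, c("feature_id", "factor", "coefficient", "eta2", "partial_eta2",
          "p_value", if (adjust) "p_adjusted", "n", "flagged")]
}

## Fast vectorized path: single predictor, no covariates.  eta2 equals the
## model R^2; the F test is the overall regression F.
.fit_single_predictor <- function(features, pred) {
  n <- nrow(features)
  X <- stats::model.matrix(~pred)
  p_terms <- ncol(X) - 1L
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, features)
  resid <- features - fitted
  center <- colMeans(features)
  ss_total <- colSums(sweep(features, 2, center)^2)
  ss_err <- colSums(resid^2)
  ss_fac <- ss_total - ss_err
  flagged <- ss_total <= .Machine$double.eps * n
  eta2 <- ifelse(flagged, 0, pmin(pmax(ss_fac / ss_total, 0), 1))
  df2 <- n - 1L - p_terms
  Fstat <- (ss_fac / p_terms) / (ss_err / df2)
  p <- ifelse(flagged, 1, pf(Fstat, p_terms, df2, lower.tail = FALSE))
  ## exact fits: F = Inf -> p = 0
  p[!flagged & ss_err <= .Machine$double.eps * ss_total] <- 0
  coefs <- if (p_terms == 1L) {
    b <- qr.coef(qrX, features)[2L, ]
    ifelse(flagged, NA_real_, b)
  } else {
    rep(NA_real_, ncol(features))
  }
  list(coefficient = coefs, eta2 = eta2, partial_eta2 = eta2,
       p_value = pmin(pmax(p, 0), 1), flagged = flagged)
}

## General path: covariates entered first, factor last; sequential
## (type-I) sums of squares via nested QR fits.
.fit_with_covariates <- function(features, pred, covs) {
  n <- nrow(features)
  d0 <- data.frame(covs)
  X0 <- stats::model.matrix(~., data = d0)
  X1 <- stats::model.matrix(~. + .pred, data = cbind(d0, .pred = pred))
  qr0 <- qr(X0)
  qr1 <- qr(X1)
  df_fac <- qr1$rank - qr0$rank
  df_err <- n - qr1$rank
  r0 <- features - qr.fitted(qr0, features)
  r1 <- features - qr.fitted(qr1, features)
  ss0 <- colSums(r0^2)
  ss1 <- colSums(r1^2)
  ss_fac <- ss0 - ss1
  center <- colMeans(features)
  ss_total <- colSums(sweep(features, 2, center)^2)
  flagged <- ss_total <= .Machine$double.eps * n
  eta2 <- ifelse(flagged, 0, pmin(pmax(ss_fac / ss_total, 0), 1))
  partial <- ifelse(flagged, 0,
                    pmin(pmax(ss_fac / (ss_fac + ss1), 0), 1))
  Fstat <- (ss_fac / df_fac) / (ss1 / df_err)
  p <- ifelse(flagged, 1, pf(Fstat, df_fac, df_err, lower.tail = FALSE))
  p[!flagged & ss1 <= .Machine$double.eps * ss_total] <- 0
  b <- if (df_fac == 1L) qr.coef(qr1, features)[ncol(X1), ] else
    rep(NA_real_, ncol(features))
  list(coefficient = ifelse(flagged, NA_real_, b),
       eta2 = eta2, partial_eta2 = partial,
       p_value = pmin(pmax(p, 0), 1), flagged = flagged)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of p-values
#' (delegates to [stats::p.adjust()] with `method = "BH"`, after domain
#' checks).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @examples
#' bhAdjust(c(0.001, 0.5, 1.0))  # 0.003, 0.75, 1.0
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-tier inclusion/exclusion filter for individual ions
#'
#' Keeps features significantly associated with genotype
#' (`p_adjusted < includeThreshold`) but not strongly associated with sex
#' (`p_adjusted > excludeThreshold`), ranks the survivors by partial
#' eta-squared (descending, ties broken lexicographically by feature id for
#' determinism), and truncates to the `topK` strongest.
#'
#' @param resultsGenotype,resultsSex outputs of [fitFeatureModels()] over
#'   the same features for the genotype and sex factors.
#' @param includeThreshold adjusted-p inclusion cutoff (default 0.01).
#' @param excludeThreshold adjusted-p sex-exclusion cutoff (default 0.05).
#' @param topK maximum number of features returned (default 100).
#' @return The surviving rows of `resultsGenotype`, ranked, with the sex
#'   effect size appended as `eta2_sex`; empty (with a warning) when nothing
#'   survives.
#' @export
selectGenotypeIons <- function(resultsGenotype, resultsSex,
                               includeThreshold = 0.01,
                               excludeThreshold = 0.05, topK = 100L) {
  if (!setequal(resultsGenotype$feature_id, resultsSex$feature_id)) {
    stop("genotype and sex results must cover the same features")
  }
  sex <- resultsSex[match(resultsGenotype$feature_id,
                          resultsSex$feature_id), ]
  keep <- resultsGenotype$p_adjusted < includeThreshold &
    sex$p_adjusted > excludeThreshold
  out <- resultsGenotype[keep, , drop = FALSE]
  out$eta2_sex <- sex$eta2[keep]
  if (!nrow(out)) {
    warning("no feature passed the inclusion/exclusion filter")
    return(out)
  }
  ord <- order(-out$partial_eta2, out$feature_id)
  out <- out[ord, , drop = FALSE]
  head(out, topK)
}

#' Select compressed category features
#'
#' Keeps compressed (CPC) features whose factor association passes
#' `p_adjusted < pThreshold`, ranked by partial eta-squared descending with
#' lexicographic tie-breaks.  No sex exclusion and no truncation.
#'
#' @param results output of [fitFeatureModels()] on the compressed feature
#'   matrix.
#' @param pThreshold adjusted-p cutoff (default 0.05).
#' @return The surviving rows, ranked; empty with a warning when nothing
#'   survives.
#' @export
selectCategoryFeatures <- function(results, pThreshold = 0.05) {
  keep <- results$p_adjusted < pThreshold
  out <- results[keep, , drop = FALSE]
  if (!nrow(out)) {
    warning("no compressed feature passed the p < ", pThreshold, " filter")
    return(out)
  }
  out[order(-out$partial_eta2, out$feature_id), , drop = FALSE]
}

#' Effect-size conversions
#'
#' `eta2ToF()` converts eta-squared to Cohen's f via
#' `f = sqrt(eta2 / (1 - eta2))`; `fToD()` converts Cohen's f to Cohen's d
#' for a univariate model with two equal-size groups, `d = 2f`.
#'
#' @param eta2 eta-squared value(s) in \[0, 1).
#' @param f Cohen's f value(s).
#' @return Numeric vector of converted effect sizes.
#' @examples
#' eta2ToF(0.22)          # 0.53 at 2 decimals
#' fToD(eta2ToF(0.22))    # 1.06 at 2 decimals
#' @export
eta2ToF <- function(eta2) {
  if (any(eta2 < 0 | eta2 >= 1)) stop("eta2 must be in [0, 1)")
  sqrt(eta2 / (1 - eta2))
}

#' @rdname eta2ToF
#' @export
fToD <- function(f) {
  if (any(f < 0)) stop("f must be nonnegative")
  2 * f
}
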