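## Tier-2 wrapper: elastic-net penalized classification (glmnet backend)
## trained with leave-one-out cross-validation, fold-internal class-imbalance
## handling (class weights or SMOTE), |beta|-based importance ranking, and
## classification metrics.

#' Elastic-net training configuration
#'
#' The penalty follows the convention in which `alpha = 1` is the pure L1
#' (lasso) limit and `alpha = 0` the ridge limit.  The mixing parameter is
#' selected from `alphaGrid` by mean leave-one-out deviance; the default
#' grid brackets the balanced default 0.5.
#'
#' @param alphaGrid candidate mixing parameters in \[0, 1\]
#'   (default `c(0.1, 0.5, 0.9)`).
#' @param lambdaGrid optional decreasing positive penalty grid; by default
#'   the glmnet path computed on the full data is used.
#' @param nLambda path length when `lambdaGrid` is `NULL` (default 50).
#' @param family `"auto"` (binomial for 2 classes, multinomial otherwise),
#'   `"binomial"`, `"multinomial"`, or `"gaussian"` (regression check mode).
#' @param imbalance `"none"`, `"class_weights"` (inverse-frequency
#'   observation weights) or `"smote"` (minority oversampling inside each
#'   training fold).
#' @param smoteK SMOTE neighbor count (default 5, clipped to class size - 1).
#' @param seed integer seed controlling SMOTE interpolation draws.
#' @param standardize standardize predictors inside the solver and report
#'   coefficients on the standardized scale (default `TRUE`).
#' @return A list of class `"enetConfig"`.
#' @export
enetConfig <- function(alphaGrid = c(0.1, 0.5, 0.9), lambdaGrid = NULL,
                       nLambda = 50L,
                       family = c("auto", "binomial", "multinomial",
                                  "gaussian"),
                       imbalance = c("none", "class_weights", "smote"),
                       smoteK = 5L, seed = 1L, standardize = TRUE) {
  family <- match.arg(family)
  imbalance <- match.arg(imbalance)
  if (any(alphaGrid < 0 | alphaGrid > 1)) stop("alpha must be in [0, 1]")
  if (!is.null(lambdaGrid) && any(lambdaGrid <= 0)) {
    stop("lambdaGrid must be positive")
  }
  structure(list(alphaGrid = alphaGrid, lambdaGrid = lambdaGrid,
                 nLambda = as.integer(nLambda), family = family,
                 imbalance = imbalance, smoteK = as.integer(smoteK),
                 seed = as.integer(seed), standardize = standardize),
            class = "enetConfig")
}

## Run code with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

.class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab[as.character(y)])
  as.numeric(w)
}

#' SMOTE minority oversampling
#'
#' Upsamples every minority class to the majority-class count by
#' interpolating synthetic points: each new point lies uniformly on the
#' segment between a randomly chosen minority sample and one of its `k`
#' nearest neighbors within the same class (Euclidean distance; `k` is
#' clipped to class size - 1).  Deterministic given `seed`.
#'
#' @param X numeric feature matrix, samples in rows.
#' @param y class labels aligned with `X` rows.
#' @param k neighbor count (default 5).
#' @param seed integer seed.
#' @return A list with the augmented `X`, `y`, and `synthetic` (logical
#'   marking the appended rows).
#' @export
smoteOversample <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  nmax <- max(tab)
  Xa <- X
  ya <- y
  .with_seed(seed, {
    for (cl in names(tab)) {
      need <- nmax - tab[[cl]]
      if (need == 0L) next
      idx <- which(y == cl)
      if (length(idx) < 2L) {
        stop("minority class '", cl, "' has a single sample; ",
             "cannot interpolate")
      }
      Xc <- X[idx, , drop = FALSE]
      kk <- min(k, length(idx) - 1L)
      D <- as.matrix(stats::dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1, function(d) order(d)[seq_len(kk)])
      nn <- matrix(nn, nrow = kk)   # kk x n_class
      base <- sample.int(length(idx), need, replace = TRUE)
      pick <- vapply(base, function(b) nn[sample.int(kk, 1L), b],
                     integer(1))
      u <- runif(need)
      synth <- Xc[base, , drop = FALSE] +
        u * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
      rownames(synth) <- sprintf("%s_smote%d", cl, seq_len(need))
      Xa <- rbind(Xa, synth)
      ya <- c(ya, rep(cl, need))
    }
  })
  list(X = Xa, y = ya, synthetic = c(rep(FALSE, nrow(X)),
                                     rep(TRUE, nrow(Xa) - nrow(X))))
}

## Per-observation deviance of glmnet predictions along the lambda path.
## prob: matrix (binomial: P(second level), nlambda cols) or array
## (n x K x nlambda, multinomial); returns n x nlambda matrix.
.loo_deviance <- function(prob, y_idx, family) {
  eps <- 1e-15
  if (family == "binomial") {
    p <- pmin(pmax(prob, eps), 1 - eps)
    out <- -2 * log(p)
    flip <- y_idx != 2L
    out[flip, ] <- -2 * log(1 - p[flip, , drop = FALSE])
    out
  } else {
    nl <- dim(prob)[3]
    out <- matrix(NA_real_, length(y_idx), nl)
    for (i in seq_along(y_idx)) {
      out[i, ] <- -2 * log(pmax(prob[i, y_idx[i], ], eps))
    }
    out
  }
}

.fit_glmnet <- function(X, y, alpha, lambda, family, weights,
                        standardize) {
  glmnet::glmnet(X, y, family = family, alpha = alpha, lambda = lambda,
                 weights = weights, standardize = standardize,
                 thresh = 1e-12, maxit = 1e6)
}

#' Train an elastic-net classifier with leave-one-out validation
#'
#' For every left-out sample the model is refit on the remaining samples
#' (with the configured imbalance handling applied to the training fold
#' only) across the full `(alpha, lambda)` grid; the penalty minimizing the
#' mean leave-one-out deviance is selected, final coefficients come from a
#' fit on all samples at that penalty, and the stored LOO predictions feed
#' the classification metrics (accuracy with exact binomial CI, unweighted
#' and linearly weighted Cohen's kappa).
#'
#' With `family = "gaussian"` (check mode) `y` is numeric, deviance is the
#' squared error, and no classification metrics are computed.
#'
#' @param X numeric feature matrix, samples in rows, no missing values.
#' @param y class labels (two or more classes, each with at least 2
#'   samples); a numeric response in gaussian mode.
#' @param config an [enetConfig()] list.
#' @param classLevels optional ordered class levels (e.g. [stageLevels()])
#'   used for the confusion matrix and the weighted kappa; default the
#'   sorted observed labels (stage labels are auto-ordered).
#' @return An [EnetResult-class].
#' @export
trainEnet <- function(X, y, config = enetConfig(), classLevels = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- sprintf("feature%d", seq_len(ncol(X)))
  }
  if (any(!is.finite(X))) stop("X contains missing or non-finite values")
  n <- nrow(X)
  family <- config$family
  if (family == "gaussian") {
    y_num <- as.numeric(y)
    lev <- NULL
  } else {
    y_chr <- as.character(y)
    if (is.null(classLevels)) {
      lev <- sort(unique(y_chr))
      if (all(lev %in% STAGE_LEVELS)) {
        lev <- STAGE_LEVELS[STAGE_LEVELS %in% lev]
      }
    } else {
      lev <- classLevels
    }
    yf <- base::factor(y_chr, levels = lev)
    tab <- table(yf)
    if (length(tab) < 2L) stop("need at least 2 classes")
    if (any(tab < 2L)) {
      stop("class(es) with a single sample: ",
           paste(names(tab)[tab < 2L], collapse = ", "),
           "; merge or remove them before training")
    }
    if (family == "auto") {
      family <- if (length(lev) == 2L) "binomial" else "multinomial"
    }
  }
  ## lambda path per alpha, from a full-data fit (shared across folds)
  full_w <- if (family != "gaussian" && config$imbalance == "class_weights") {
    .class_weights(yf)
  } else {
    rep(1, n)
  }
  paths <- lapply(config$alphaGrid, function(a) {
    if (!is.null(config$lambdaGrid)) return(sort(config$lambdaGrid,
                                                 decreasing = TRUE))
    f <- .fit_glmnet(X, if (family == "gaussian") y_num else yf,
                     alpha = max(a, 1e-3), lambda = NULL, family = family,
                     weights = full_w, standardize = config$standardize)
    lam <- f$lambda
    if (length(lam) > config$nLambda) {
      lam <- lam[round(seq(1, length(lam), length.out = config$nLambda))]
    }
    lam
  })

  best <- list(dev = Inf)
  for (ai in seq_along(config$alphaGrid)) {
    a <- config$alphaGrid[[ai]]
    lam <- paths[[ai]]
    dev <- matrix(NA_real_, n, length(lam))
    prob_store <- vector("list", n)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      if (family == "gaussian") {
        fit <- .fit_glmnet(Xtr, y_num[-i], a, lam, family, rep(1, n - 1L),
                           config$standardize)
        pr <- predict(fit, X[i, , drop = FALSE], s = lam)
        dev[i, ] <- (y_num[i] - as.numeric(pr))^2
        prob_store[[i]] <- as.numeric(pr)
        next
      }
      ytr <- yf[-i]
      w <- rep(1, n - 1L)
      if (config$imbalance == "class_weights") {
        w <- .class_weights(ytr)
      } else if (config$imbalance == "smote") {
        aug <- smoteOversample(Xtr, as.character(ytr), k = config$smoteK,
                               seed = config$seed + i)
        Xtr <- aug$X
        ytr <- base::factor(aug$y, levels = lev)
        w <- rep(1, nrow(Xtr))
      }
      fit <- .fit_glmnet(Xtr, ytr, a, lam, family, w, config$standardize)
      pr <- predict(fit, X[i, , drop = FALSE], s = lam, type = "response")
      if (family == "binomial") {
        prob_i <- as.numeric(pr)   # P(second level), one per lambda
        dev[i, ] <- .loo_deviance(matrix(prob_i, 1), as.integer(yf)[i],
                                  "binomial")
        prob_store[[i]] <- prob_i
      } else {
        ## pr: 1 x K x nlambda
        dev[i, ] <- .loo_deviance(pr, as.integer(yf)[i], "multinomial")
        prob_store[[i]] <- pr[1, , , drop = TRUE]   # K x nlambda
      }
    }
    mdev <- colMeans(dev)
    j <- which.min(mdev)
    if (mdev[j] < best$dev) {
      best <- list(dev = mdev[j], alpha = a, lambda = lam[j],
                   lambda_path = lam, lambda_idx = j,
                   prob_store = prob_store)
    }
  }

  ## final fit on all data at the selected penalty
  yy <- if (family == "gaussian") y_num else yf
  Xfin <- X
  yfin <- yy
  wfin <- full_w
  if (family != "gaussian" && config$imbalance == "smote") {
    aug <- smoteOversample(X, as.character(yf), k = config$smoteK,
                           seed = config$seed)
    Xfin <- aug$X
    yfin <- base::factor(aug$y, levels = lev)
    wfin <- rep(1, nrow(Xfin))
  }
  fit <- .fit_glmnet(Xfin, yfin, best$alpha, best$lambda_path, family,
                     wfin, config$standardize)
  cf <- .coef_matrix(fit, best$lambda, family, colnames(X), lev)
  if (config$standardize) {
    ## report on the standardized predictor scale so |beta| is comparable
    sds <- apply(X, 2, sd)
    cf$beta <- cf$beta * sds
  }

  if (family == "gaussian") {
    loo <- DataFrame(sample = rownames(X) %||% as.character(seq_len(n)),
                     observed = y_num,
                     predicted = vapply(best$prob_store,
                                        function(p) p[best$lambda_idx],
                                        numeric(1)))
    res <- new("EnetResult", coefficients = cf$beta,
               intercepts = cf$a0, alpha = best$alpha,
               lambda = best$lambda, family = family,
               looPredictions = loo, importance = DataFrame(),
               confusion = matrix(0, 0, 0), metrics = list(),
               config = unclass(config))
    return(res)
  }

  j <- best$lambda_idx
  prob <- t(vapply(best$prob_store, function(p) {
    if (family == "binomial") c(1 - p[j], p[j]) else p[, j]
  }, numeric(length(lev))))
  colnames(prob) <- lev
  pred <- lev[max.col(prob, ties.method = "first")]
  met <- classificationMetrics(pred, as.character(yf), levels = lev)
  loo <- DataFrame(sample = rownames(X) %||% as.character(seq_len(n)),
                   observed = as.character(yf), predicted = pred)
  for (cl in lev) loo[[paste0("prob.", cl)]] <- prob[, cl]
  res <- new("EnetResult", coefficients = cf$beta, intercepts = cf$a0,
             alpha = best$alpha, lambda = best$lambda, family = family,
             looPredictions = loo, importance = DataFrame(),
             confusion = met$confusion, metrics = met[c(
               "accuracy", "accuracy_ci", "kappa_unweighted",
               "kappa_weighted")],
             config = unclass(config))
  res@importance <- importanceScores(res)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.coef_matrix <- function(fit, lambda, family, feat, lev) {
  cc <- coef(fit, s = lambda)
  if (family == "multinomial") {
    beta <- do.call(cbind, lapply(cc, function(m) as.numeric(m[-1, 1])))
    a0 <- vapply(cc, function(m) m[1, 1], numeric(1))
    colnames(beta) <- lev
    names(a0) <- lev
  } else {
    beta <- matrix(as.numeric(cc[-1, 1]), ncol = 1)
    colnames(beta) <- if (!is.null(lev)) lev[2] else "response"
    a0 <- setNames(cc[1, 1], colnames(beta))
  }
  rownames(beta) <- feat
  list(beta = beta, a0 = a0)
}

#' Importance scores from elastic-net coefficients
#'
#' Per-class importance is the absolute value of each (class, feature)
#' coefficient, globally rescaled so the largest overall score (the sum of a
#' feature's per-class scores) equals 100.  Zero coefficients score 0; an
#' all-zero model yields all-zero scores with a warning.  Scores are
#' invariant to rescaling all coefficients.
#'
#' @param object an [EnetResult-class].
#' @param ... unused.
#' @return A `DataFrame`, one row per feature, with one score column per
#'   class, an `overall` column (the row sum), sorted by `overall`
#'   descending.
#' @export
setMethod("importanceScores", "EnetResult", function(object, ...) {
  b <- abs(object@coefficients)
  overall <- rowSums(b)
  if (max(overall) == 0) {
    warning("all coefficients are zero; importance is all zero")
    s <- 0
  } else {
    s <- 100 / max(overall)
  }
  sc <- b * s
  out <- DataFrame(feature = rownames(b))
  for (j in seq_len(ncol(sc))) out[[colnames(b)[j]]] <- sc[, j]
  out$overall <- rowSums(sc)
  out[order(-out$overall, out$feature), ]
})

#' Classification metrics for leave-one-out predictions
#'
#' Accuracy with an exact (Clopper-Pearson) 95 percent binomial confidence
#' interval, the class x class confusion matrix, and Cohen's kappa in its
#' unweighted and weighted forms.  The weighted kappa uses linear
#' disagreement weights over the ordinal class ordering by default
#' (quadratic available), so near-miss errors between adjacent disease
#' stages are discounted.
#'
#' @param predicted,observed class label vectors of equal length.
#' @param levels ordered class levels (default: sorted observed union, with
#'   disease-stage labels auto-ordered).
#' @param weighting `"linear"` (default) or `"quadratic"` disagreement
#'   weights for the weighted kappa.
#' @param conf.level confidence level of the accuracy CI (default 0.95).
#' @return A list: `accuracy`, `accuracy_ci`, `kappa_unweighted`,
#'   `kappa_weighted`, `confusion`.
#' @examples
#' classificationMetrics(rep(c("a", "b"), c(60, 40)),
#'                       rep(c("a", "b"), c(50, 50)))
#' @export
classificationMetrics <- function(predicted, observed, levels = NULL,
                                  weighting = c("linear", "quadratic"),
                                  conf.level = 0.95) {
  weighting <- match.arg(weighting)
  predicted <- as.character(predicted)
  observed <- as.character(observed)
  stopifnot(length(predicted) == length(observed))
  if (is.null(levels)) {
    levels <- sort(unique(c(observed, predicted)))
    if (all(levels %in% STAGE_LEVELS)) {
      levels <- STAGE_LEVELS[STAGE_LEVELS %in% levels]
    }
  }
  ob <- base::factor(observed, levels = levels)
  pr <- base::factor(predicted, levels = levels)
  confusion <- unclass(table(observed = ob, predicted = pr))
  n <- length(observed)
  correct <- sum(diag(confusion))
  accuracy <- correct / n
  ci <- as.numeric(binom.test(correct, n,
                              conf.level = conf.level)$conf.int)
  if (length(unique(observed)) < 2L) {
    warning("observed labels contain a single class; kappa is undefined")
    ku <- kw <- NaN
  } else {
    ku <- .cohen_kappa(confusion, weights = "none")
    kw <- .cohen_kappa(confusion, weights = weighting)
  }
  list(accuracy = accuracy, accuracy_ci = ci, kappa_unweighted = ku,
       kappa_weighted = kw, confusion = confusion)
}

## Cohen's kappa from a confusion matrix; disagreement weights d_ij are 0
## (unweighted: 0/1), |i-j|/(K-1) (linear) or its square (quadratic), and
## kappa = 1 - sum(d * observed) / sum(d * expected).
.cohen_kappa <- function(confusion, weights = c("none", "linear",
                                                "quadratic")) {
  weights <- match.arg(weights)
  K <- nrow(confusion)
  n <- sum(confusion)
  p_obs <- confusion / n
  p_exp <- outer(rowSums(confusion), colSums(confusion)) / n^2
  d <- abs(outer(seq_len(K), seq_len(K), "-"))
  d <- switch(weights,
              none = (d > 0) * 1,
              linear = d / (K - 1),
              quadratic = (d / (K - 1))^2)
  1 - sum(d * p_obs) / sum(d * p_exp)
}
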