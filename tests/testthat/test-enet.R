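test_that("huge penalty collapses to the null model", {
  set.seed(1)
  X <- matrix(rnorm(40 * 8), 40, 8)
  y <- rep(c("a", "b"), c(25, 15))
  fit <- suppressWarnings(trainEnet(
    X, y, enetConfig(alphaGrid = 0.5, lambdaGrid = c(1e6, 2e6), seed = 1)))
  expect_true(all(fit@coefficients == 0))
  ## null-model LOO predictions cannot beat the majority rule
  expect_true(all(looPredictions(fit)$predicted %in% c("a", "b")))
})

test_that("ridge limit matches the closed form at alpha = 0", {
  set.seed(2)
  X <- matrix(rnorm(10 * 5), 10, 5)
  y <- rnorm(10)
  lam <- c(0.5, 0.1)
  fit <- trainEnet(X, y, enetConfig(alphaGrid = 0, lambdaGrid = lam,
                                    family = "gaussian",
                                    standardize = FALSE, seed = 1))
  ## the gaussian solver standardizes the response internally, so its
  ## quadratic penalty at a user lambda equals the textbook ridge penalty
  ## at lambda / sd(y) (population sd); the closed form checks that exact
  ## solution
  sy <- sqrt(mean((y - mean(y))^2))
  oracle <- ridge_closed_form(X, y, fit@lambda / sy)
  expect_equal(unname(fit@coefficients[, 1]), as.numeric(oracle),
               tolerance = 1e-6)
})

test_that("pure-L1 limit matches a coordinate-descent lasso at alpha = 1", {
  set.seed(3)
  for (r in 1:3) {
    X <- matrix(rnorm(10 * 5), 10, 5)
    b <- c(2, -1, 0, 0, 0.5)
    y <- as.numeric(X %*% b + rnorm(10, sd = 0.3))
    lam <- c(0.3, 0.05)
    fit <- trainEnet(X, y, enetConfig(alphaGrid = 1, lambdaGrid = lam,
                                      family = "gaussian",
                                      standardize = FALSE, seed = 1))
    oracle <- lasso_coordinate_descent(X, y, fit@lambda)
    expect_equal(unname(fit@coefficients[, 1]), oracle, tolerance = 1e-5)
  }
})

test_that("sparsity is monotone along the lambda path", {
  set.seed(4)
  X <- matrix(rnorm(50 * 20), 50, 20)
  y <- as.numeric(X[, 1] - X[, 2] + rnorm(50, sd = 0.5))
  lam <- exp(seq(log(1), log(1e-3), length.out = 20))
  f <- glmnet::glmnet(X, y, alpha = 0.5, lambda = lam)
  nz <- colSums(as.matrix(f$beta) != 0)
  expect_true(all(diff(nz) >= 0))   # lambda decreasing -> nonzeros grow
})

test_that("well-separated classes reach near-perfect LOO accuracy", {
  accs <- numeric(3)
  for (s in 1:3) {
    set.seed(s)
    n <- 40
    X <- matrix(rnorm(n * 100), n, 100)
    y <- rep(c("case", "ctrl"), each = n / 2)
    X[y == "case", 1:10] <- X[y == "case", 1:10] + 3
    fit <- trainEnet(X, y, enetConfig(alphaGrid = 0.5, seed = s))
    accs[s] <- classMetrics(fit)$accuracy
  }
  expect_gte(mean(accs), 0.95)
})

test_that("importance scores are additive, max-100 and scale-invariant", {
  res <- new("EnetResult",
             coefficients = matrix(c(0.5, 0, -0.2, 0, 0.3, 0.05), 3, 2,
                                   dimnames = list(c("f1", "f2", "f3"),
                                                   c("A", "B"))),
             intercepts = c(A = 0, B = 0), alpha = 0.5, lambda = 0.1,
             family = "multinomial", looPredictions = S4Vectors::DataFrame(),
             importance = S4Vectors::DataFrame(),
             confusion = matrix(0, 0, 0), metrics = list(), config = list())
  imp <- as.data.frame(importanceScores(res))
  expect_equal(imp$overall, imp$A + imp$B)
  expect_equal(max(imp$overall), 100)
  ## single nonzero coefficient -> that feature scores 100
  res2 <- res
  res2@coefficients <- matrix(c(0, 0.7, 0, 0, 0, 0), 3, 2,
                              dimnames = dimnames(res@coefficients))
  imp2 <- as.data.frame(importanceScores(res2))
  expect_equal(imp2$overall[imp2$feature == "f2"], 100)
  expect_equal(sum(imp2$overall), 100)
  ## doubling all coefficients changes nothing
  res3 <- res
  res3@coefficients <- res@coefficients * 2
  expect_equal(as.data.frame(importanceScores(res3)),
               as.data.frame(importanceScores(res)))
  res4 <- res
  res4@coefficients[] <- 0
  expect_warning(imp4 <- importanceScores(res4), "all coefficients")
  expect_true(all(as.data.frame(imp4)$overall == 0))
})

test_that("SMOTE balances classes by convex interpolation", {
  set.seed(6)
  X <- matrix(rnorm(48 * 4), 48, 4)
  y <- rep(c("maj", "min"), c(36, 12))
  out <- smoteOversample(X, y, k = 5, seed = 9)
  expect_equal(unname(table(out$y)["min"]), 36L)
  expect_equal(unname(table(out$y)["maj"]), 36L)
  expect_equal(sum(out$synthetic), 24L)
  ## every synthetic point is a convex combination of two real minority
  ## points: residual of projection onto some pair's segment is ~0
  minX <- X[y == "min", , drop = FALSE]
  synth <- out$X[out$synthetic, , drop = FALSE]
  pairs <- utils::combn(nrow(minX), 2)
  on_segment <- function(p) {
    any(apply(pairs, 2, function(ij) {
      a <- minX[ij[1], ]; b <- minX[ij[2], ]
      d <- b - a
      t <- sum((p - a) * d) / sum(d * d)
      t >= -1e-9 && t <= 1 + 1e-9 &&
        sqrt(sum((a + t * d - p)^2)) < 1e-8
    }))
  }
  expect_true(all(apply(synth, 1, on_segment)))
  ## balanced input returned unchanged; determinism; singleton error
  bal <- smoteOversample(X[1:24, ], rep(c("a", "b"), each = 12), seed = 1)
  expect_equal(nrow(bal$X), 24)
  out2 <- smoteOversample(X, y, k = 5, seed = 9)
  expect_identical(out$X, out2$X)
  expect_error(smoteOversample(X[1:13, ], rep(c("a", "b"), c(12, 1))),
               "single sample")
})

test_that("imbalance handling raises minority recall on a 36-vs-12 design", {
  recall <- function(fit, cls) {
    cm <- confusionMatrix(fit)
    cm[cls, cls] / sum(cm[cls, ])
  }
  rec <- matrix(NA_real_, 3, 3,
                dimnames = list(NULL, c("none", "class_weights", "smote")))
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 48
    X <- matrix(rnorm(n * 20), n, 20)
    y <- rep(c("maj", "min"), c(36, 12))
    ## weak signal so the unweighted fit leans on the majority class
    X[y == "min", 1:4] <- X[y == "min", 1:4] + 1.0
    for (imb in colnames(rec)) {
      fit <- suppressWarnings(trainEnet(
        X, y, enetConfig(alphaGrid = 0.5, imbalance = imb, seed = s)))
      rec[s, imb] <- recall(fit, "min")
    }
  }
  m <- colMeans(rec)
  expect_gt(m["class_weights"], m["none"])
  expect_gt(m["smote"], m["none"])
})

test_that("classification metrics match hand computations", {
  ## 2x2 confusion ((40,10),(20,30)): accuracy 0.7, p_e 0.5, kappa 0.4
  obs <- rep(c("a", "a", "b", "b"), c(40, 10, 20, 30))
  pred <- rep(c("a", "b", "a", "b"), c(40, 10, 20, 30))
  m <- classificationMetrics(pred, obs)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$kappa_unweighted, 0.4, tolerance = 1e-12)
  expect_equal(m$kappa_unweighted, kappa_bruteforce(obs, pred),
               tolerance = 1e-12)
  ## CI is exact binomial and contains the accuracy
  expect_equal(m$accuracy_ci,
               as.numeric(binom.test(70, 100)$conf.int))
  ## perfect agreement
  p <- classificationMetrics(obs, obs)
  expect_equal(p$accuracy, 1)
  expect_equal(p$kappa_unweighted, 1)
  expect_equal(p$kappa_weighted, 1)
  ## single-class truth: kappa undefined
  expect_warning(
    s <- classificationMetrics(rep("a", 5), rep("a", 5)), "single class")
  expect_true(is.nan(s$kappa_unweighted))
})

test_that("independent predictions give kappa near zero", {
  set.seed(8)
  n <- 10000
  obs <- sample(c("a", "b", "c"), n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  pred <- sample(c("a", "b", "c"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  m <- classificationMetrics(pred, obs)
  expect_lt(abs(m$kappa_unweighted), 0.03)
  expect_lt(abs(m$kappa_weighted), 0.03)
})

test_that("weighted kappa discounts adjacent-stage confusions", {
  obs <- rep(stageLevels(), each = 10)
  pred <- obs
  pred[1:5] <- "non-lesional"       # adjacent miss
  m_adj <- classificationMetrics(pred, obs)
  pred2 <- obs
  pred2[1:5] <- "advanced"          # maximal miss, same count
  m_far <- classificationMetrics(pred2, obs)
  expect_equal(m_adj$kappa_unweighted, m_far$kappa_unweighted,
               tolerance = 1e-12)
  expect_gt(m_adj$kappa_weighted, m_far$kappa_weighted)
  expect_gt(m_adj$kappa_weighted, m_adj$kappa_unweighted)
})

test_that("degenerate class sizes are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(trainEnet(X, rep(c("a", "b"), c(9, 1))), "single sample")
  expect_error(trainEnet(X, rep("a", 10)), "2 classes")
  X[1, 1] <- NA
  expect_error(trainEnet(X, rep(c("a", "b"), 5)), "non-finite")
})
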