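test_that("eta-squared matches a hand ANOVA decomposition", {
  ## two groups of 4: SS_between = 8, SS_total = 18, eta2 = 4/9
  y <- c(1, 2, 3, 4, 3, 4, 5, 6)
  g <- rep(c("WT", "cpdm"), each = 4)
  md <- data.frame(sex = rep("F", 8), genotype = g,
                   stage = ifelse(g == "WT", "control", "advanced"))
  res <- fitFeatureModels(matrix(y, 8, 1), md, factor = "genotype")
  expect_equal(res$eta2, 8 / 18, tolerance = 1e-12)
  expect_equal(res$eta2, eta2_bruteforce(y, g), tolerance = 1e-12)
  ## perfect separation: feature equal to the group indicator
  res2 <- fitFeatureModels(matrix(as.numeric(g == "cpdm"), 8, 1), md,
                           factor = "genotype")
  expect_equal(res2$eta2, 1)
  expect_lt(res2$p_value, 1e-12)
})

test_that("eta2 equals squared Pearson correlation for a binary predictor", {
  set.seed(17)
  n <- 30
  g <- rep(c("WT", "cpdm"), each = n / 2)
  md <- data.frame(sex = rep(c("F", "M"), n / 2), genotype = g,
                   stage = ifelse(g == "WT", "control", "established"))
  X <- matrix(rnorm(n * 20), n, 20)
  res <- fitFeatureModels(X, md, factor = "genotype")
  r2 <- apply(X, 2, function(v) cor(v, as.numeric(g == "cpdm"))^2)
  expect_equal(res$eta2, unname(r2), tolerance = 1e-10)
})

test_that("null features have mean eta2 near 1/(n-1)", {
  set.seed(23)
  n <- 72
  md <- as.data.frame(tiny_sample_data(4))[rep(1:4, 18), ]
  X <- matrix(rnorm(n * 1000), n, 1000)
  res <- fitFeatureModels(X, md, factor = "genotype", adjust = FALSE)
  expect_equal(mean(res$eta2), 1 / (n - 1), tolerance = 0.15)
})

test_that("progression enters as a monotone ordinal trend", {
  expect_equal(progressionCoding(c("control", "advanced", "established")),
               c(0, 3, 2))
  expect_error(progressionCoding("lesional"), "unknown stage")
  set.seed(29)
  im <- small_sim(seed = 4, nIons = 60)
  md <- as.data.frame(SummarizedExperiment::colData(im))
  score <- progressionCoding(md$stage)
  X <- matrix(score + rnorm(72, sd = 0.4), 72, 1)
  res_num <- fitFeatureModels(X, md, factor = "progression")
  res_cat <- fitFeatureModels(X, md, factor = "progression",
                              progression = "categorical")
  expect_gt(res_num$eta2, 0.5)
  ## categorical model can only explain at least as much variance
  expect_gte(res_cat$eta2 + 1e-10, res_num$eta2)
})

test_that("covariate-adjusted models use sequential SS with factor last", {
  set.seed(37)
  n <- 24
  md <- data.frame(sex = rep(c("F", "M"), n / 2),
                   genotype = rep(c("WT", "cpdm"), each = n / 2),
                   stage = rep(c("control", "advanced"), each = n / 2))
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 1] <- X[, 1] + 2 * (md$genotype == "cpdm") + 1 * (md$sex == "M")
  res <- fitFeatureModels(X, md, factor = "genotype", covariates = "sex")
  ## oracle: anova() sequential decomposition on the same model
  fit <- lm(X[, 1] ~ factor(md$sex) + factor(md$genotype))
  a <- anova(fit)
  ss <- a$`Sum Sq`
  expect_equal(res$eta2[1], ss[2] / sum(ss), tolerance = 1e-10)
  expect_equal(res$partial_eta2[1], ss[2] / (ss[2] + ss[3]),
               tolerance = 1e-10)
  expect_equal(res$p_value[1], a$`Pr(>F)`[2], tolerance = 1e-10)
  expect_gte(res$partial_eta2[1], res$eta2[1])
})

test_that("constant features are flagged with eta2 0 and p 1", {
  md <- as.data.frame(tiny_sample_data(8))
  X <- cbind(rep(2, 8), rnorm(8))
  res <- fitFeatureModels(X, md, factor = "genotype")
  expect_true(res$flagged[1])
  expect_equal(res$eta2[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_false(res$flagged[2])
})

test_that("BH adjustment matches the brute-force step-up", {
  expect_equal(bhAdjust(0.031), 0.031)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(0.001, 0.5, 1.0)), c(0.003, 0.75, 1.0))
  set.seed(41)
  for (m in c(2, 5, 20)) {
    p <- runif(m)^2
    expect_equal(bhAdjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  ## permutation invariance and monotonicity
  p <- runif(15)
  perm <- sample(15)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  p2 <- p
  p2[3] <- min(1, p2[3] + 0.2)
  expect_true(all(bhAdjust(p2) >= bhAdjust(p) - 1e-12))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("inclusion/exclusion filter applies both thresholds and ranks", {
  rg <- data.frame(feature_id = c("a", "b", "c", "d"),
                   factor = "genotype", coefficient = 1,
                   eta2 = c(0.5, 0.6, 0.3, 0.2),
                   partial_eta2 = c(0.5, 0.6, 0.3, 0.2),
                   p_value = 0.001, p_adjusted = c(0.001, 0.001, 0.5, 0.001),
                   n = 72, flagged = FALSE)
  rs <- data.frame(feature_id = c("a", "b", "c", "d"),
                   factor = "sex", coefficient = 0,
                   eta2 = 0.01, partial_eta2 = 0.01, p_value = 0.5,
                   p_adjusted = c(0.5, 0.01, 0.5, 0.7), n = 72,
                   flagged = FALSE)
  sel <- selectGenotypeIons(rg, rs)
  ## "b" is sex-confounded (sex p_adj 0.01 < 0.05); "c" fails inclusion
  expect_equal(sel$feature_id, c("a", "d"))
  expect_equal(sel$eta2_sex, c(0.01, 0.01))
  ## ranking by partial eta2 descending, then truncation
  sel1 <- selectGenotypeIons(rg, rs, topK = 1)
  expect_equal(sel1$feature_id, "a")
  expect_warning(selectGenotypeIons(rg[3, ], rs[3, ]), "no feature")
})

test_that("category-feature selection keeps p < threshold without exclusion", {
  res <- data.frame(feature_id = c("x CPC 1", "x CPC 2", "y CPC 1"),
                    factor = "genotype", coefficient = 1,
                    eta2 = c(0.4, 0.1, 0.6),
                    partial_eta2 = c(0.4, 0.1, 0.6),
                    p_value = c(0.01, 0.06, 0.001),
                    p_adjusted = c(0.04, 0.06, 0.003), n = 72,
                    flagged = FALSE)
  sel <- selectCategoryFeatures(res)
  expect_equal(sel$feature_id, c("y CPC 1", "x CPC 1"))
  expect_warning(selectCategoryFeatures(res, pThreshold = 0.001),
                 "no compressed feature")
})

test_that("planted genotype-only ions dominate the top of the filter", {
  ## 40 genotype-only and 40 sex-only ions among 950 nulls: at this scale
  ## the closure backlash of a concentrated shift (k/p ~ 0.04) is
  ## negligible, so the filter should recover the planted ions
  tt <- syntheticTransitionTable(defaultCategorySizes(1030))
  hits <- numeric(5)
  for (s in seq_len(5)) {
    im <- simulateLipidomics(simConfig(
      nIons = 1030, effects = planted_effects(tt), zeroRate = 0, seed = s))
    truth <- S4Vectors::metadata(im)$truth
    planted <- truth$transition_id[truth$factor == "genotype"]
    lrm <- clr(im)
    X <- t(SummarizedExperiment::assay(lrm, "logratio"))
    md <- SummarizedExperiment::colData(im)
    rg <- fitFeatureModels(X, md, "genotype")
    rs <- fitFeatureModels(X, md, "sex")
    sel <- selectGenotypeIons(rg, rs, topK = 40)
    hits[s] <- mean(head(sel$feature_id, 40) %in% planted)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("effect-size conversions follow the closed forms", {
  expect_equal(round(eta2ToF(0.22), 2), 0.53)
  expect_equal(round(fToD(eta2ToF(0.22)), 2), 1.06)
  expect_equal(eta2ToF(0), 0)
  expect_equal(fToD(0), 0)
  expect_equal(eta2ToF(0.5), 1)
  expect_equal(fToD(eta2ToF(0.5)), 2)
  expect_error(eta2ToF(1), "\\[0, 1\\)")
})
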