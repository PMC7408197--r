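test_that("the default design reproduces the study layout", {
  im <- simulateLipidomics(simConfig(seed = 7))
  expect_equal(dim(im), c(1030L, 72L))
  md <- as.data.frame(sampleData(im))
  expect_equal(unname(table(md$genotype)), c(36L, 36L),
               ignore_attr = TRUE)
  ## 12 samples per genotype x age cell (6 males + 6 females)
  expect_true(all(table(md$genotype, md$age_weeks) == 12L))
  expect_true(all(table(md$sex, md$genotype, md$age_weeks) == 6L))
  ## stage labels: control iff WT, one disease stage per age
  expect_true(all((md$stage == "control") == (md$genotype == "WT")))
  expect_equal(sort(unique(md$stage[md$age_weeks == 5 &
                                    md$genotype == "cpdm"])),
               "non-lesional")
  ## 10 categories summing to 1030
  expect_equal(sum(defaultCategorySizes()), 1030L)
  expect_setequal(unique(transitions(im)$category), lipidCategories())
})

test_that("generation is deterministic in the seed", {
  a <- small_sim(seed = 5, nIons = 50)
  b <- small_sim(seed = 5, nIons = 50)
  c <- small_sim(seed = 6, nIons = 50)
  expect_identical(intensities(a), intensities(b))
  expect_false(identical(intensities(a), intensities(c)))
  ## generator does not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(small_sim(seed = 5, nIons = 20))
  expect_identical(rnorm(1), before)
})

test_that("a no-effect configuration yields null per-ion effect sizes", {
  im <- simulateLipidomics(simConfig(nIons = 150, effects = list(),
                                     zeroRate = 0, seed = 21))
  X <- t(logRatios(clr(im)))
  md <- sampleData(im)
  n <- ncol(im)
  ## under the null, per-ion eta2 for a 1-df predictor is Beta(1/2, (n-2)/2)
  q95 <- qbeta(0.95, 1 / 2, (n - 2) / 2)
  for (fac in c("sex", "genotype", "progression")) {
    res <- fitFeatureModels(X, md, factor = fac, adjust = FALSE)
    expect_gte(mean(res$eta2 <= q95), 0.90)
    expect_equal(mean(res$eta2), 1 / (n - 1), tolerance = 0.3)
  }
})

test_that("concentrated effects realize the target eta-squared", {
  ## Monte-Carlo check of the calibration against the per-ion ANOVA oracle
  meds <- numeric(8)
  for (s in seq_len(8)) {
    tt <- syntheticTransitionTable(defaultCategorySizes(200))
    eff <- effectSpec("genotype", targetEta2 = 0.6,
                      style = "concentrated",
                      transitions = tt$transition_id[1:50])
    im <- simulateLipidomics(simConfig(nIons = 200, effects = list(eff),
                                       zeroRate = 0, seed = 300 + s))
    X <- t(logRatios(clr(im)))
    md <- as.data.frame(sampleData(im))
    planted <- S4Vectors::metadata(im)$truth$transition_id
    e2 <- vapply(planted, function(id) {
      eta2_bruteforce(X[, id], md$genotype)
    }, numeric(1))
    meds[s] <- median(e2)
  }
  expect_lt(abs(mean(meds) - 0.6), 0.1)
})

test_that("stage effects are monotone in the stage ordering", {
  tt <- syntheticTransitionTable(defaultCategorySizes(100))
  eff <- effectSpec("progression", targetEta2 = 0.7,
                    style = "concentrated",
                    transitions = tt$transition_id[1:10])
  im <- simulateLipidomics(simConfig(nIons = 100, effects = list(eff),
                                     zeroRate = 0, seed = 31))
  X <- t(logRatios(clr(im)))
  md <- as.data.frame(sampleData(im))
  for (id in tt$transition_id[1:5]) {
    stage_means <- tapply(X[, id], md$stage, mean)[stageLevels()]
    expect_true(all(diff(stage_means) > 0))
  }
})

test_that("the planted-truth ledger records every targeted ion", {
  im <- small_sim(seed = 41, nIons = 120)
  truth <- S4Vectors::metadata(im)$truth
  expect_setequal(unique(truth$factor), c("sex", "genotype", "progression"))
  expect_true(all(truth$transition_id %in% transitions(im)$transition_id))
  ## diffuse effects carry balanced signs
  sex_delta <- truth$delta[truth$factor == "sex"]
  expect_lt(abs(mean(sign(sex_delta))), 0.1)
  ## concentrated effects are one-signed
  gen_delta <- truth$delta[truth$factor == "genotype"]
  expect_true(all(gen_delta > 0))
})

test_that("zero injection respects the configured rate", {
  im <- small_sim(seed = 51, nIons = 150, zeroRate = 0.05)
  frac <- mean(intensities(im) == 0)
  expect_lt(abs(frac - 0.05), 0.01)
  expect_error(simConfig(zeroRate = 0.5), "zeroRate")
})

test_that("infeasible calibration and bad configs are rejected", {
  expect_error(effectSpec("genotype", targetEta2 = 0.97), "infeasible")
  expect_error(simConfig(nPerCell = 1), "nPerCell")
  expect_error(simConfig(nIons = 100,
                         categorySizes = c(phospholipid = 50)),
               "sum to nIons")
  expect_error(effectSpec("progression", 0.5,
                          stageProfile = c(3, 2, 1, 0)),
               "nondecreasing")
})

test_that("simulation configs round-trip through YAML", {
  cfg <- simConfig(nIons = 60, seed = 17, zeroRate = 0.05,
                   effects = list(effectSpec("genotype", 0.4,
                                             categories = "phospholipid",
                                             nTargets = 5L)))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeSimConfig(cfg, path)
  cfg2 <- readSimConfig(path)
  expect_equal(cfg2$nIons, 60L)
  expect_equal(cfg2$seed, 17L)
  expect_equal(cfg2$effects[[1]]$targetEta2, 0.4)
  expect_equal(intensities(simulateLipidomics(cfg)),
               intensities(simulateLipidomics(cfg2)), tolerance = 1e-12)
})
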