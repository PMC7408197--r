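## Synthetic-data generator emulating the study's statistical structure:
## a balanced 2 (genotype) x 2 (sex) x 3 (age) design with 6 samples per
## cell, ~1030 monitored lipid ions in 10 annotated categories, log-normal
## intensities closed to compositions, a diffuse sex effect spread over many
## ions, a concentrated genotype effect in phospholipid / glycerolipid
## categories, and a monotone ordinal disease-stage effect -- with per-ion
## target eta-squared calibrated on the log scale.

#' Default per-category ion counts
#'
#' A phospholipid-heavy allocation of ions over the ten categories.  The
#' exact per-category counts of the motivating study are not published, so
#' these defaults are a plausible assumption, not a constant; pass
#' `categorySizes` to [simConfig()] to override.  When `nIons` differs from
#' the default total (1030) the allocation is rescaled proportionally.
#'
#' @param nIons total ion count (default 1030).
#' @return Named integer vector over [lipidCategories()] summing to `nIons`.
#' @export
defaultCategorySizes <- function(nIons = 1030L) {
  base <- c(
    "phospholipid" = 400L,
    "sphingolipid" = 150L,
    "glycerolipid" = 150L,
    "acylcarnitine" = 80L,
    "cholesteryl-ester" = 60L,
    "DAG" = 50L,
    "phospholipid-or-cholesteryl-ester" = 40L,
    "phospholipid-or-glycerolipid" = 40L,
    "acylcarnitine-or-glycerolipid" = 30L,
    "sphingolipid-or-glycerolipid" = 30L
  )
  if (nIons == sum(base)) return(base)
  sizes <- round(base * nIons / sum(base))
  sizes[sizes < 1L] <- 1L
  ## fix rounding so the total is exact, adjusting the largest category
  sizes[1] <- sizes[1] + (nIons - sum(sizes))
  sizes
}

#' Specify a planted factor effect
#'
#' Describes one multiplicative (log-scale) effect planted on a set of
#' target ions, calibrated so the realized per-ion eta-squared of a linear
#' model on the log-ratio scale approximates `targetEta2`.
#'
#' @param factor `"sex"`, `"genotype"` or `"progression"`.
#' @param targetEta2 desired per-ion eta-squared in \[0, 0.95\].
#' @param categories category labels the target ions are drawn from
#'   (default: all).
#' @param transitions explicit transition ids (overrides `categories`).
#' @param style `"concentrated"` (all target ions shift the same way) or
#'   `"diffuse"` (random balanced signs across target ions, emulating an
#'   effect dispersed over many lipids without moving the geometric mean).
#' @param nTargets number of target ions sampled from the category pool
#'   (default: all of it).
#' @param stageProfile monotone nondecreasing per-stage multipliers for
#'   progression effects (default `c(0, 1, 2, 3)` over
#'   control < non-lesional < established < advanced).
#' @return A list of class `"effectSpec"`.
#' @export
effectSpec <- function(factor = c("sex", "genotype", "progression"),
                       targetEta2, categories = NULL, transitions = NULL,
                       style = c("concentrated", "diffuse"),
                       nTargets = NULL, stageProfile = c(0, 1, 2, 3)) {
  factor <- match.arg(factor)
  style <- match.arg(style)
  if (targetEta2 < 0 || targetEta2 > 0.95) {
    stop("infeasible calibration: targetEta2 must be in [0, 0.95]")
  }
  if (any(diff(stageProfile) < 0) || length(stageProfile) != 4L) {
    stop("stageProfile must be 4 nondecreasing multipliers")
  }
  structure(list(factor = factor, targetEta2 = targetEta2,
                 categories = categories, transitions = transitions,
                 style = style, nTargets = nTargets,
                 stageProfile = stageProfile),
            class = "effectSpec")
}

#' Default planted effects emulating the study conditions
#'
#' A diffuse sex effect over many ions of all categories, a concentrated
#' genotype effect in the phospholipid / glycerolipid categories, and a
#' monotone ordinal disease-progression effect over phospholipids,
#' cholesteryl esters, acylcarnitines and sphingolipids.
#'
#' @return A list of [effectSpec()] objects.
#' @export
defaultEffects <- function() {
  list(
    effectSpec("sex", targetEta2 = 0.15, style = "diffuse",
               nTargets = 300L),
    effectSpec("genotype", targetEta2 = 0.60, style = "concentrated",
               categories = c("phospholipid", "glycerolipid",
                              "phospholipid-or-glycerolipid"),
               nTargets = 60L),
    effectSpec("progression", targetEta2 = 0.50, style = "concentrated",
               categories = c("phospholipid", "cholesteryl-ester",
                              "acylcarnitine", "sphingolipid"),
               nTargets = 50L)
  )
}

#' Simulation configuration
#'
#' @param nPerCell samples per sex x genotype x age cell (default 6; >= 2).
#' @param ages three age groups in weeks (default `c(5, 7, 10)`), mapped in
#'   increasing order to the non-lesional, established and advanced stages
#'   of the mutant genotype.
#' @param nIons total monitored ion count (default 1030).
#' @param categorySizes named counts per category summing to `nIons`
#'   (default [defaultCategorySizes()]).
#' @param baseLogMean,baseLogSd log-normal baseline: mean log-intensity and
#'   within-ion noise SD on the log scale (defaults `log(1e5)` and 0.5).
#' @param ionBaselineSd SD of per-ion baseline log-abundances (default 1.5),
#'   giving ions realistically unequal abundances.
#' @param effects list of [effectSpec()]s (default [defaultEffects()]).
#' @param zeroRate fraction of cells forced to zero, completely at random
#'   (default 0.02; <= 0.2).
#' @param seed integer RNG seed (default 1).
#' @return A list of class `"simConfig"`.
#' @export
simConfig <- function(nPerCell = 6L, ages = c(5L, 7L, 10L), nIons = 1030L,
                      categorySizes = NULL, baseLogMean = log(1e5),
                      baseLogSd = 0.5, ionBaselineSd = 1.5,
                      effects = defaultEffects(), zeroRate = 0.02,
                      seed = 1L) {
  if (nPerCell < 2L) stop("nPerCell must be >= 2")
  if (length(ages) != 3L) stop("exactly 3 age groups are required")
  if (zeroRate < 0 || zeroRate > 0.2) stop("zeroRate must be in [0, 0.2]")
  if (is.null(categorySizes)) categorySizes <- defaultCategorySizes(nIons)
  if (sum(categorySizes) != nIons) {
    stop("categorySizes must sum to nIons (", nIons, ")")
  }
  if (!all(names(categorySizes) %in% LIPID_CATEGORIES)) {
    stop("categorySizes names must be category labels")
  }
  for (e in effects) {
    if (!inherits(e, "effectSpec")) stop("effects must be effectSpec objects")
  }
  structure(list(nPerCell = as.integer(nPerCell), ages = sort(ages),
                 nIons = as.integer(nIons), categorySizes = categorySizes,
                 baseLogMean = baseLogMean, baseLogSd = baseLogSd,
                 ionBaselineSd = ionBaselineSd, effects = effects,
                 zeroRate = zeroRate, seed = as.integer(seed)),
            class = "simConfig")
}

## Distinct diagnostic product ions per category keep (Q1, Q3) triples
## separated by more than the default 0.5 Th matching tolerances; Q1 values
## sit on a 1 Th grid per category (unit-resolution spacing).
.category_fragment <- c(
  "acylcarnitine" = 85.1,
  "acylcarnitine-or-glycerolipid" = 89.1,
  "cholesteryl-ester" = 369.3,
  "DAG" = 239.2,
  "glycerolipid" = 155.1,
  "phospholipid" = 184.1,
  "phospholipid-or-cholesteryl-ester" = 190.1,
  "phospholipid-or-glycerolipid" = 196.1,
  "sphingolipid" = 264.3,
  "sphingolipid-or-glycerolipid" = 270.3
)

#' Synthetic transition method table
#'
#' Builds a plausible [TransitionTable-class] for simulation: each category
#' carries a distinct diagnostic product ion (pairwise separated by several
#' Th) and precursor m/z values on a 1 Th grid starting at 400.6 Th, so all
#' (Q1, Q3, polarity) triples stay unambiguous at the default 0.5 Th
#' matching tolerances.
#'
#' @param categorySizes named per-category ion counts.
#' @return A [TransitionTable-class].
#' @export
syntheticTransitionTable <- function(categorySizes = defaultCategorySizes()) {
  cats <- rep(names(categorySizes), categorySizes)
  q1 <- unlist(lapply(categorySizes,
                      function(n) 400.6 + seq_len(n) - 1L))
  q3 <- .category_fragment[cats]
  TransitionTable(
    precursor_mz = round(q1, 1), product_mz = unname(q3),
    polarity = "positive", collision_energy = 20,
    attribution = sprintf("synthetic %s ion", cats),
    category = cats
  )
}

.design_metadata <- function(config) {
  stages_by_age <- setNames(STAGE_LEVELS[2:4], as.character(config$ages))
  rows <- expand.grid(rep = seq_len(config$nPerCell),
                      sex = c("F", "M"), age_weeks = config$ages,
                      genotype = c("WT", "cpdm"),
                      stringsAsFactors = FALSE)
  rows$stage <- ifelse(rows$genotype == "WT", "control",
                       stages_by_age[as.character(rows$age_weeks)])
  rownames(rows) <- sprintf("S%03d", seq_len(nrow(rows)))
  DataFrame(rows[, c("sex", "genotype", "age_weeks", "stage")],
            row.names = rownames(rows))
}

## Per-sample numeric effect carrier for one factor.
.effect_carrier <- function(meta, spec) {
  switch(spec$factor,
    sex = as.numeric(meta$sex == "M"),
    genotype = as.numeric(meta$genotype == "cpdm"),
    progression = spec$stageProfile[match(meta$stage, STAGE_LEVELS)]
  )
}

#' Generate a synthetic MRM-profiling dataset
#'
#' Draws log-normal intensities for the configured balanced design and
#' plants each configured effect as a multiplicative log-scale shift on its
#' target ions.  The shift magnitude is calibrated from the ANOVA identity
#' `eta2 = var_between / (var_between + sigma^2)`: for a carrier `c` (group
#' indicator, or monotone stage profile) the per-ion shift is
#' `delta = sigma * sqrt(eta2 / (1 - eta2)) / sd(c)`, so the realized
#' eta-squared of a per-ion linear model approaches `targetEta2` in the
#' large-n limit.  Diffuse effects get random balanced signs across their
#' target ions so the per-sample geometric mean (and hence the CLR
#' reference) is left nearly unchanged.
#'
#' @param config a [simConfig()].
#' @return An [IntensityMatrix-class]; `metadata()$truth` holds the
#'   planted-effect ledger (one row per targeted ion and factor with the
#'   signed log-scale shift), and `metadata()$config` the configuration.
#' @examples
#' im <- simulateLipidomics(simConfig(nIons = 40, seed = 7))
#' im
#' head(S4Vectors::metadata(im)$truth)
#' @export
simulateLipidomics <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  tt <- syntheticTransitionTable(config$categorySizes)
  meta <- .design_metadata(config)
  n <- nrow(meta)
  p <- nrow(tt)
  truth <- list()
  .with_seed(config$seed, {
    mu <- rnorm(p, config$baseLogMean, config$ionBaselineSd)
    L <- matrix(rnorm(n * p, 0, config$baseLogSd), n, p)
    L <- sweep(L, 2, mu, "+")
    for (ei in seq_along(config$effects)) {
      spec <- config$effects[[ei]]
      if (!is.null(spec$transitions)) {
        idx <- match(spec$transitions, tt$transition_id)
        if (any(is.na(idx))) stop("unknown target transition id(s)")
      } else {
        pool <- if (is.null(spec$categories)) seq_len(p) else
          which(tt$category %in% spec$categories)
        if (!length(pool)) stop("effect ", ei, ": empty target pool")
        nt <- min(spec$nTargets %||% length(pool), length(pool))
        idx <- sort(sample(pool, nt))
      }
      carrier <- .effect_carrier(meta, spec)
      sdc <- sqrt(mean((carrier - mean(carrier))^2))
      if (sdc == 0) stop("effect ", ei, ": carrier is constant")
      delta <- config$baseLogSd *
        sqrt(spec$targetEta2 / (1 - spec$targetEta2)) / sdc
      if (spec$style == "concentrated") {
        ## closure correction: a same-sign shift of k of p ions moves the
        ## per-sample geometric mean by (k/p) * delta, attenuating the CLR
        ## contrast to delta * (1 - k/p); rescale so the target eta2 is
        ## realized on the CLR scale.  A shift of every ion is pure scale
        ## and unobservable in relative data.
        atten <- 1 - length(idx) / p
        if (atten <= 0) {
          stop("effect ", ei, ": a concentrated effect covering every ion ",
               "is unobservable on the log-ratio scale")
        }
        delta <- delta / atten
      }
      sgn <- if (spec$style == "diffuse") {
        s <- rep(c(1, -1), length.out = length(idx))
        sample(s)
      } else {
        rep(1, length(idx))
      }
      L[, idx] <- L[, idx] + outer(carrier, sgn * delta)
      truth[[ei]] <- data.frame(
        effect = ei, factor = spec$factor, style = spec$style,
        transition_id = tt$transition_id[idx],
        category = tt$category[idx],
        target_eta2 = spec$targetEta2, delta = sgn * delta
      )
    }
    X <- exp(L)
    if (config$zeroRate > 0) {
      X[runif(n * p) < config$zeroRate] <- 0
    }
    ## no all-zero samples or ions (zeros are MCAR, so this is rare)
    X[rowSums(X) == 0, 1] <- exp(config$baseLogMean)
    dimnames(X) <- list(rownames(meta), tt$transition_id)
    im <- IntensityMatrix(t(X), tt, meta)
    metadata(im)$truth <- do.call(rbind, truth) %||%
      data.frame(transition_id = character())
    metadata(im)$config <- config
    im
  })
}

#' Read / write a simulation configuration as YAML
#'
#' @param path YAML file path.
#' @return `readSimConfig()`: a [simConfig()]; `writeSimConfig()`: `path`,
#'   invisibly.
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  effects <- lapply(y$effects, function(e) {
    do.call(effectSpec, e[!vapply(e, is.null, logical(1))])
  })
  cs <- if (!is.null(y$categorySizes)) unlist(y$categorySizes) else NULL
  simConfig(
    nPerCell = y$nPerCell %||% 6L, ages = y$ages %||% c(5L, 7L, 10L),
    nIons = y$nIons %||% 1030L, categorySizes = cs,
    baseLogMean = y$baseLogMean %||% log(1e5),
    baseLogSd = y$baseLogSd %||% 0.5,
    ionBaselineSd = y$ionBaselineSd %||% 1.5,
    effects = if (length(effects)) effects else defaultEffects(),
    zeroRate = y$zeroRate %||% 0.02, seed = y$seed %||% 1L
  )
}

#' @rdname readSimConfig
#' @param config a [simConfig()].
#' @export
writeSimConfig <- function(config, path) {
  y <- unclass(config)
  y$effects <- lapply(y$effects, unclass)
  y$categorySizes <- as.list(y$categorySizes)
  yaml::write_yaml(y, path, precision = 15L)
  invisible(path)
}
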