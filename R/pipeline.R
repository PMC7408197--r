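## Config-driven orchestration of the published analyses: preprocessing ->
## (per-category CPC compression | individual ions) -> univariate filter ->
## elastic-net ranking -> metrics, with plot-ready table export.

.analysis_factor <- c(sex_binary = "sex", genotype_binary = "genotype",
                      progression_multiclass = "progression")

#' Run one end-to-end analysis
#'
#' Executes the full pipeline on an intensity matrix: closure, zero
#' replacement and log-ratio transformation; either per-category CPC
#' compression or individual-ion features; the univariate filter for the
#' chosen factor; elastic-net training with leave-one-out validation; and
#' classification metrics.  All randomized stages (SMOTE draws, target
#' sampling) derive from `seed`.
#'
#' For `individual_ions` the inclusion/exclusion filter is used (factor
#' association adjusted p below `includeThreshold`, sex association
#' adjusted p above `excludeThreshold`, top `topK` by partial eta-squared);
#' `sex_binary` cannot exclude on itself and uses the plain
#' `p < pThreshold` filter.  For `compressed_categories` the plain filter is
#' used with `pThreshold`.
#'
#' @param data an [IntensityMatrix-class].
#' @param analysis `"genotype_binary"`, `"sex_binary"` or
#'   `"progression_multiclass"`.
#' @param featureMode `"compressed_categories"` or `"individual_ions"`.
#' @param transform log-ratio transform for individual-ion features
#'   (`"clr"`, default, or `"ilr"`).
#' @param varianceTarget per-category retained variance (default 0.95).
#' @param deltaFraction zero-replacement delta fraction (default 0.65).
#' @param pThreshold adjusted-p cutoff of the plain univariate filter
#'   (default 0.05).
#' @param includeThreshold,excludeThreshold,topK inclusion/exclusion filter
#'   parameters for individual ions (defaults 0.01, 0.05, 100).
#' @param enet an [enetConfig()]; the default uses class weights for the
#'   multiclass analysis and no imbalance handling otherwise, with `seed`.
#' @param seed integer seed recorded in the run manifest and used for every
#'   random stage.
#' @param outputDir optional directory: when given, all intermediate and
#'   final tables plus a run manifest are written there.
#' @return A report bundle (list): `analysis`, `featureMode`, `features`
#'   (the feature matrix), `univariate` (all per-feature models),
#'   `univariateSex` (for the exclusion filter, when fitted), `selected`
#'   (the surviving ranked features), `cpc` (per-category
#'   [CompressedFeatureSet-class]s, compressed mode), `enet`
#'   ([EnetResult-class] or `NULL` if nothing survived), `metrics`,
#'   `importance`, `seed`, `manifest`.
#' @export
runAnalysis <- function(data,
                        analysis = c("genotype_binary", "sex_binary",
                                     "progression_multiclass"),
                        featureMode = c("compressed_categories",
                                        "individual_ions"),
                        transform = c("clr", "ilr"),
                        varianceTarget = 0.95, deltaFraction = 0.65,
                        pThreshold = 0.05, includeThreshold = 0.01,
                        excludeThreshold = 0.05, topK = 100L,
                        enet = NULL, seed = 1L, outputDir = NULL) {
  analysis <- match.arg(analysis)
  featureMode <- match.arg(featureMode)
  transform <- match.arg(transform)
  stopifnot(is(data, "IntensityMatrix"))
  meta <- colData(data)
  fac <- .analysis_factor[[analysis]]

  cpc_sets <- NULL
  if (featureMode == "compressed_categories") {
    cc <- compressCategories(data, varianceTarget = varianceTarget,
                             deltaFraction = deltaFraction)
    features <- cc$features
    cpc_sets <- cc$sets
  } else {
    lrm <- if (transform == "clr") {
      clr(data, deltaFraction = deltaFraction)
    } else {
      ilr(data, deltaFraction = deltaFraction)
    }
    features <- t(assay(lrm, "logratio"))
  }

  uni <- fitFeatureModels(features, meta, factor = fac)
  uni_sex <- NULL
  if (featureMode == "individual_ions" && fac != "sex") {
    uni_sex <- fitFeatureModels(features, meta, factor = "sex")
    selected <- selectGenotypeIons(uni, uni_sex,
                                   includeThreshold = includeThreshold,
                                   excludeThreshold = excludeThreshold,
                                   topK = topK)
  } else {
    selected <- selectCategoryFeatures(uni, pThreshold = pThreshold)
    if (featureMode == "individual_ions") selected <- head(selected, topK)
  }

  if (is.null(enet)) {
    enet <- enetConfig(
      imbalance = if (analysis == "progression_multiclass")
        "class_weights" else "none",
      seed = seed
    )
  }
  y <- switch(fac, sex = meta$sex, genotype = meta$genotype,
              progression = meta$stage)
  fit <- NULL
  importance <- NULL
  metrics <- NULL
  if (nrow(selected) >= 2L) {
    X <- features[, selected$feature_id, drop = FALSE]
    fit <- trainEnet(X, y, config = enet)
    importance <- importanceScores(fit)
    metrics <- classMetrics(fit)
  } else {
    warning("fewer than 2 features survived the univariate filter; ",
            "elastic-net step skipped")
  }

  bundle <- list(
    analysis = analysis, featureMode = featureMode, features = features,
    univariate = uni, univariateSex = uni_sex, selected = selected,
    cpc = cpc_sets, enet = fit, importance = importance,
    metrics = metrics, transitions = as.data.frame(rowData(data)),
    seed = seed,
    manifest = list(
      package = "lipidCPC",
      version = as.character(utils::packageVersion("lipidCPC")),
      analysis = analysis, featureMode = featureMode, seed = seed,
      n_samples = ncol(data), n_transitions = nrow(data),
      n_selected = nrow(selected),
      enet = unclass(enet)
    )
  )
  if (!is.null(outputDir)) .write_bundle(bundle, outputDir)
  bundle
}

.write_bundle <- function(bundle, outputDir) {
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  pre <- file.path(outputDir, sprintf("%s_%s", bundle$analysis,
                                      bundle$featureMode))
  write.csv(bundle$univariate, paste0(pre, "_univariate.csv"),
            row.names = FALSE)
  write.csv(bundle$selected, paste0(pre, "_selected.csv"),
            row.names = FALSE)
  if (!is.null(bundle$enet)) {
    write.csv(as.data.frame(bundle$importance, optional = TRUE),
              paste0(pre, "_importance.csv"), row.names = FALSE)
    ## per-sample class probabilities: parallel-plot-ready table
    write.csv(as.data.frame(looPredictions(bundle$enet)),
              paste0(pre, "_loo_predictions.csv"), row.names = FALSE)
    m <- bundle$metrics
    jsonlite::write_json(
      list(accuracy = m$accuracy, accuracy_ci = m$accuracy_ci,
           kappa_unweighted = m$kappa_unweighted,
           kappa_weighted = m$kappa_weighted,
           confusion = as.data.frame(unclass(bundle$enet@confusion))),
      paste0(pre, "_metrics.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, paste0(pre, "_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outputDir)
}

.annotate_features <- function(ids, transitions) {
  m <- match(ids, transitions$transition_id)
  data.frame(
    Category = ifelse(is.na(m), "compressed feature",
                      transitions$category[m]),
    `Tentative Attributions` = ifelse(is.na(m), ids,
                                      transitions$attribution[m]),
    MRM = ifelse(is.na(m), NA_character_, sprintf(
      "%g→%g", transitions$precursor_mz[m],
      transitions$product_mz[m])),
    check.names = FALSE
  )
}

#' Export publication-style result tables
#'
#' Builds the three table layouts of the reported analyses from a
#' [runAnalysis()] bundle: the univariate ranking (feature annotation plus
#' per-factor eta-squared), the binary importance ranking (single importance
#' score), and the multiclass importance ranking (per-class scores plus an
#' `Overall` column equal to their row sum).  Effect sizes and importance
#' scores are rounded to 2 decimals.  Empty selections yield header-only
#' tables with a warning.
#'
#' @param bundle a [runAnalysis()] report bundle.
#' @param outputDir optional directory to write the CSVs into.
#' @return A list of `data.frame`s: `univariate`, and `importance` (binary
#'   or multiclass layout depending on the fitted family).
#' @export
makeTables <- function(bundle, outputDir = NULL) {
  sel <- bundle$selected
  uni_tab <- if (nrow(sel)) {
    ann <- .annotate_features(sel$feature_id, bundle$transitions)
    tab <- cbind(ann, round(sel[, c("eta2", "partial_eta2"), drop = FALSE],
                            2))
    names(tab)[names(tab) == "eta2"] <-
      sprintf("%s (eta2)", tools::toTitleCase(bundle$univariate$factor[1]))
    names(tab)[names(tab) == "partial_eta2"] <- "Partial eta2"
    if ("eta2_sex" %in% colnames(sel)) {
      tab[["Sex (eta2)"]] <- round(sel$eta2_sex, 3)
    }
    tab
  } else {
    warning("empty selection; univariate table has no rows")
    .annotate_features(character(0), bundle$transitions)
  }
  imp_tab <- NULL
  if (!is.null(bundle$enet)) {
    imp <- as.data.frame(bundle$importance, optional = TRUE)
    ann <- .annotate_features(imp$feature, bundle$transitions)
    score_cols <- setdiff(colnames(imp), c("feature", "overall"))
    scores <- round(imp[, score_cols, drop = FALSE], 2)
    if (bundle$enet@family == "multinomial") {
      colnames(scores) <- tools::toTitleCase(score_cols)
      imp_tab <- cbind(ann, scores, Overall = round(imp$overall, 2))
    } else {
      imp_tab <- cbind(ann, `Importance Score` = round(imp$overall, 2))
    }
    imp_tab <- imp_tab[order(-imp_tab[[ncol(imp_tab)]]), ]
    rownames(imp_tab) <- NULL
  }
  out <- list(univariate = uni_tab, importance = imp_tab)
  if (!is.null(outputDir)) {
    if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
    pre <- file.path(outputDir, sprintf("%s_%s", bundle$analysis,
                                        bundle$featureMode))
    write.csv(uni_tab, paste0(pre, "_table_univariate.csv"),
              row.names = FALSE)
    if (!is.null(imp_tab)) {
      write.csv(imp_tab, paste0(pre, "_table_importance.csv"),
                row.names = FALSE)
    }
  }
  out
}
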