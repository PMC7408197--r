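## Reading transition method tables and mzML SRM chromatograms; building the
## samples x transitions intensity matrix.

#' Read a transition method table
#'
#' Parses a delimited-text method table into a [TransitionTable-class].
#' Required columns: `precursor_mz`, `product_mz`, `polarity`, `category`;
#' optional: `transition_id` (default `"Q1->Q3"`), `collision_energy`,
#' `attribution`.  Duplicate (precursor, product, polarity) triples are
#' rejected.
#'
#' @param path file path.
#' @param sep field separator (default `","`).
#' @return A [TransitionTable-class].
#' @export
readMethodTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c("precursor_mz", "product_mz", "polarity", "category")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("method table schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  for (col in c("precursor_mz", "product_mz")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("non-numeric ", col, " in row(s): ",
           paste(bad, collapse = ", "))
    }
    df[[col]] <- v
  }
  TransitionTable(
    transition_id = if ("transition_id" %in% colnames(df))
      df$transition_id else NULL,
    precursor_mz = df$precursor_mz,
    product_mz = df$product_mz,
    polarity = df$polarity,
    collision_energy = if ("collision_energy" %in% colnames(df))
      df$collision_energy else NA_real_,
    attribution = if ("attribution" %in% colnames(df))
      df$attribution else NA_character_,
    category = df$category
  )
}

#' Write a transition method table to CSV
#'
#' @param transitions a [TransitionTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMethodTable <- function(transitions, path) {
  write.csv(as.data.frame(transitions), path, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample manifest
#'
#' The manifest maps each sample to its mzML files and metadata: columns
#' `sample_id`, `files` (paths separated by `";"`), `sex`, `genotype`,
#' `age_weeks`, `stage`.  Sample identity is taken from the manifest, never
#' parsed from filenames.
#'
#' @param path manifest CSV path.
#' @return `readSampleManifest()`: a list with `files` (named list of path
#'   vectors per sample) and `sampleData` (a `DataFrame`).
#' @export
readSampleManifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "files", "sex", "genotype", "age_weeks", "stage")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop("manifest schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  files <- strsplit(df$files, ";", fixed = TRUE)
  names(files) <- df$sample_id
  sd <- DataFrame(df[, c("sex", "genotype", "age_weeks", "stage")],
                  row.names = df$sample_id)
  list(files = files, sampleData = sd)
}

#' @rdname readSampleManifest
#' @param files named list of mzML path vectors per sample.
#' @param sampleData per-sample metadata aligned with `names(files)`.
#' @export
writeSampleManifest <- function(files, sampleData, path) {
  df <- data.frame(
    sample_id = names(files),
    files = vapply(files, paste, character(1), collapse = ";"),
    as.data.frame(sampleData),
    row.names = NULL
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## SRM chromatogram table of one mzML file: q1/q3 targets + summed points.
.read_srm_file <- function(path, statistic) {
  if (!file.exists(path)) stop("cannot read mzML file: ", path)
  h <- tryCatch(mzR::openMSfile(path),
                error = function(e) stop("ill-formed mzML file '", path,
                                         "': ", conditionMessage(e)))
  on.exit(suppressWarnings(mzR::close(h)))   # quiet pwiz finalizer chatter
  ## a method file may legitimately hold zero chromatograms; the backend
  ## warns about its uninitialized chromatogram list in that case
  hdr <- suppressWarnings(mzR::chromatogramHeader(h))
  if (is.null(hdr) || nrow(hdr) == 0L) {
    return(data.frame(q1 = numeric(), q3 = numeric(), value = numeric()))
  }
  keep <- which(is.finite(hdr$precursorIsolationWindowTargetMZ) &
                is.finite(hdr$productIsolationWindowTargetMZ))
  if (!length(keep)) {
    return(data.frame(q1 = numeric(), q3 = numeric(), value = numeric()))
  }
  value <- vapply(keep, function(i) {
    pts <- mzR::chromatogram(h, hdr$chromatogramIndex[i])
    v <- pts[[2]]
    switch(statistic, sum = sum(v), mean = mean(v), max = max(v))
  }, numeric(1))
  data.frame(q1 = hdr$precursorIsolationWindowTargetMZ[keep],
             q3 = hdr$productIsolationWindowTargetMZ[keep],
             value = value)
}

#' Extract transition intensities from mzML files
#'
#' For every sample, locates in its mzML files the SRM chromatogram whose
#' Q1 and Q3 isolation targets match each monitored transition within
#' tolerance, and aggregates the chromatogram intensity points over the full
#' injection window (sum by default; flow injection has no chromatographic
#' peak to integrate).  Values from multiple files carrying the same
#' transition are summed (duplicates indicate reinjection).  Transitions
#' with no matching chromatogram in any of a sample's files yield 0 with a
#' warning.  Two chromatograms matching the same transition within one file
#' indicate an over-wide tolerance and raise an error.
#'
#' @param files named list: `sample_id -> character vector of mzML paths`,
#'   e.g. from [readSampleManifest()].
#' @param transitions a [TransitionTable-class].
#' @param sampleData per-sample metadata (`sex`, `genotype`, `age_weeks`,
#'   `stage`) aligned with `names(files)`.
#' @param q1Tol,q3Tol matching tolerances in Th (default 0.5,
#'   unit-resolution triple quadrupole).
#' @param statistic aggregation of chromatogram points: `"sum"` (default),
#'   `"mean"` or `"max"`.
#' @return An [IntensityMatrix-class] covering every sample and transition.
#' @export
extractIntensities <- function(files, transitions, sampleData,
                               q1Tol = 0.5, q3Tol = 0.5,
                               statistic = c("sum", "mean", "max")) {
  statistic <- match.arg(statistic)
  stopifnot(q1Tol > 0, q3Tol > 0)
  samples <- names(files)
  if (is.null(samples)) stop("'files' must be a named list of samples")
  nt <- nrow(transitions)
  M <- matrix(0, nt, length(samples),
              dimnames = list(transitions$transition_id, samples))
  unmatched <- character()
  for (s in samples) {
    hit <- logical(nt)
    for (f in files[[s]]) {
      tab <- .read_srm_file(f, statistic)
      if (!nrow(tab)) next
      for (j in seq_len(nt)) {
        m <- which(abs(tab$q1 - transitions$precursor_mz[j]) <= q1Tol &
                   abs(tab$q3 - transitions$product_mz[j]) <= q3Tol)
        if (length(m) > 1L) {
          stop("ambiguous match: ", length(m), " chromatograms in '", f,
               "' match transition ", transitions$transition_id[j],
               "; narrow q1Tol/q3Tol")
        }
        if (length(m) == 1L) {
          M[j, s] <- M[j, s] + tab$value[m]
          hit[j] <- TRUE
        }
      }
    }
    if (!all(hit)) {
      unmatched <- c(unmatched, sprintf(
        "%s: %d transition(s) unmatched", s, sum(!hit)))
    }
  }
  if (length(unmatched)) {
    warning("unmatched transitions set to 0 -- ",
            paste(unmatched, collapse = "; "))
  }
  IntensityMatrix(M, transitions, sampleData)
}

#' Merge intensity matrices over disjoint transition subsets
#'
#' Concatenates partial intensity matrices (e.g. one per injection method)
#' covering pairwise disjoint transition sets over the same samples into a
#' single matrix over the union of transitions.
#'
#' @param parts list of [IntensityMatrix-class] objects.
#' @return A single [IntensityMatrix-class].
#' @export
mergeInjections <- function(parts) {
  stopifnot(length(parts) >= 1L)
  if (length(parts) == 1L) return(parts[[1]])
  s0 <- colnames(parts[[1]])
  for (p in parts[-1]) {
    if (!setequal(colnames(p), s0)) {
      stop("alignment error: parts cover different sample sets")
    }
  }
  ids <- lapply(parts, function(p) rowData(p)$transition_id)
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids)) {
    stop("disjointness error: transition(s) present in more than one part: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  parts <- lapply(parts, function(p) p[, s0])
  cd0 <- colData(parts[[1]])
  for (p in parts[-1]) {
    if (!identical(as.data.frame(colData(p)), as.data.frame(cd0))) {
      stop("alignment error: sample metadata differs between parts")
    }
  }
  out <- do.call(rbind, parts)
  new("IntensityMatrix", out)
}

#' Export / import an intensity matrix as wide CSV
#'
#' The wide CSV has samples in rows and transition ids in columns; sample
#' metadata travels in a sidecar CSV.
#'
#' @param object an [IntensityMatrix-class].
#' @param file matrix CSV path.
#' @param metadataFile sidecar metadata CSV path (default
#'   `<file>.metadata.csv`).
#' @return `file`, invisibly.
#' @export
writeIntensityMatrix <- function(object, file,
                                 metadataFile = paste0(file,
                                                       ".metadata.csv")) {
  wide <- t(assay(object, "intensity"))
  df <- data.frame(sample_id = rownames(wide), wide, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, file, row.names = FALSE)
  md <- data.frame(sample_id = rownames(wide),
                   as.data.frame(colData(object)), row.names = NULL)
  write.csv(md, metadataFile, row.names = FALSE)
  invisible(file)
}

#' @rdname writeIntensityMatrix
#' @param transitions a [TransitionTable-class] annotating the columns; by
#'   default a minimal table is reconstructed from `"Q1->Q3"` column names.
#' @export
readIntensityMatrix <- function(file,
                                metadataFile = paste0(file,
                                                      ".metadata.csv"),
                                transitions = NULL) {
  df <- read.csv(file, check.names = FALSE)
  md <- read.csv(metadataFile)
  wide <- as.matrix(df[, -1, drop = FALSE])
  rownames(wide) <- df$sample_id
  if (is.null(transitions)) {
    parts <- strsplit(colnames(wide), "->", fixed = TRUE)
    transitions <- TransitionTable(
      transition_id = colnames(wide),
      precursor_mz = as.numeric(vapply(parts, `[`, "", 1L)),
      product_mz = as.numeric(vapply(parts, `[`, "", 2L)),
      category = rep(LIPID_CATEGORIES[6], ncol(wide))
    )
  }
  sd <- DataFrame(md[, setdiff(colnames(md), "sample_id"), drop = FALSE],
                  row.names = md$sample_id)
  IntensityMatrix(t(wide), transitions, sd[rownames(wide), ])
}
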