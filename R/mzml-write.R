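## Minimal standard-conformant mzML 1.1.0 writer for SRM chromatogram
## fixtures.  Binary data are uncompressed little-endian 64-bit floats,
## base64-encoded; each (sample, transition) cell becomes one selected
## reaction monitoring chromatogram whose intensity points sum to the cell
## value.  Output is verified by read-back through mzR elsewhere in the
## package tests.

.enc64d <- function(x) {
  jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                endian = "little"))
}

.chromatogram_xml <- function(index, q1, q3, time, intensity) {
  tenc <- .enc64d(time)
  ienc <- .enc64d(intensity)
  paste0(
    '      <chromatogram index="', index, '" id="SRM SIC Q1=', q1,
    ' Q3=', q3, '" defaultArrayLength="', length(time), '">\n',
    '        <cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>\n',
    '        <precursor><isolationWindow>\n',
    '          <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="', q1,
    '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '        </isolationWindow><activation>\n',
    '          <cvParam cvRef="MS" accession="MS:1000133" name="collision-induced dissociation" value=""/>\n',
    '        </activation></precursor>\n',
    '        <product><isolationWindow>\n',
    '          <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="', q3,
    '" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
    '        </isolationWindow></product>\n',
    '        <binaryDataArrayList count="2">\n',
    '          <binaryDataArray encodedLength="', nchar(tenc), '">\n',
    '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000595" name="time array" value="" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>\n',
    '            <binary>', tenc, '</binary>\n',
    '          </binaryDataArray>\n',
    '          <binaryDataArray encodedLength="', nchar(ienc), '">\n',
    '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
    '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
    '            <binary>', ienc, '</binary>\n',
    '          </binaryDataArray>\n',
    '        </binaryDataArrayList>\n',
    '      </chromatogram>\n'
  )
}

.mzml_document <- function(run_id, chromatograms) {
  paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <cvList count="2">\n',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
    '    <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
    '  </cvList>\n',
    '  <fileDescription><fileContent>\n',
    '    <cvParam cvRef="MS" accession="MS:1001473" name="selected reaction monitoring chromatogram" value=""/>\n',
    '  </fileContent></fileDescription>\n',
    '  <softwareList count="1"><software id="sw" version="0.1">',
    '<cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="lipidCPC fixture writer"/>',
    '</software></softwareList>\n',
    '  <instrumentConfigurationList count="1"><instrumentConfiguration id="ic">',
    '<cvParam cvRef="MS" accession="MS:1000031" name="instrument model" value=""/>',
    '</instrumentConfiguration></instrumentConfigurationList>\n',
    '  <dataProcessingList count="1"><dataProcessing id="dp">',
    '<processingMethod order="1" softwareRef="sw">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>',
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    '  <run id="', run_id, '" defaultInstrumentConfigurationRef="ic">\n',
    '    <chromatogramList count="', length(chromatograms),
    '" defaultDataProcessingRef="dp">\n',
    paste(chromatograms, collapse = ""),
    '    </chromatogramList>\n',
    '  </run>\n',
    '</mzML>\n'
  )
}

#' Write mzML chromatogram fixtures for an intensity matrix
#'
#' Emits minimal standard-conformant mzML files containing one SRM
#' chromatogram per (sample, transition) cell, with intensity points summing
#' to the cell value.  Transitions are partitioned into `nMethods` contiguous
#' blocks mirroring a multi-injection acquisition, giving `nMethods` files
#' per sample (a file may hold zero chromatograms; zero-valued cells are
#' omitted and read back as 0).  A sample manifest and the method table are
#' written alongside.
#'
#' @param object an [IntensityMatrix-class].
#' @param outDir output directory (created if needed).
#' @param pointsPerChromatogram intensity points per chromatogram
#'   (default 3; the cell value is split evenly so the points sum to it).
#' @param nMethods number of injection methods / files per sample
#'   (default 6).
#' @return Invisibly, a list with `files` (named list of per-sample path
#'   vectors), `manifest` and `methodTable` paths.
#' @export
emitMzmlFixtures <- function(object, outDir, pointsPerChromatogram = 3L,
                             nMethods = 6L) {
  stopifnot(is(object, "IntensityMatrix"), pointsPerChromatogram >= 1L)
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outDir)
  }
  tt <- rowData(object)
  vals <- assay(object, "intensity")
  nt <- nrow(vals)
  method <- ceiling(seq_len(nt) * nMethods / nt)   # contiguous blocks
  np <- pointsPerChromatogram
  tgrid <- seq_len(np) - 1
  files <- list()
  for (s in colnames(vals)) {
    paths <- character(nMethods)
    for (m in seq_len(nMethods)) {
      idx <- which(method == m & vals[, s] > 0)
      chroms <- character(0)
      if (length(idx)) {
        chroms <- vapply(seq_along(idx), function(ii) {
          j <- idx[ii]
          .chromatogram_xml(ii - 1L, tt$precursor_mz[j], tt$product_mz[j],
                            tgrid, rep(vals[j, s] / np, np))
        }, character(1))
      }
      path <- file.path(outDir, sprintf("%s_method%d.mzML", s, m))
      writeLines(.mzml_document(sprintf("%s_m%d", s, m), chroms), path,
                 sep = "")
      paths[m] <- path
    }
    files[[s]] <- paths
  }
  manifest <- file.path(outDir, "manifest.csv")
  writeSampleManifest(files, colData(object), manifest)
  method_table <- file.path(outDir, "transitions.csv")
  writeMethodTable(new("TransitionTable", as(tt, "DFrame")), method_table)
  invisible(list(files = files, manifest = manifest,
                 methodTable = method_table))
}
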