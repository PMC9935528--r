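#' @include synthetic.R
NULL

.write_manifest <- function(outDir, inputs, counts = NULL, extra = list()) {
  manifest <- c(list(
    package = "gloriaqc",
    version = as.character(packageVersion("gloriaqc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  ), extra)
  if (!is.null(counts)) manifest$flag_counts <- as.list(counts)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' File-to-file quality control
#'
#' Reads a reflectance table in the GLORIA layout, runs the full QC suite,
#' and writes `GLORIA_qc_flags.csv`, `GLORIA_qc_ancillary.csv` and a
#' `manifest.json` (inputs with checksums, package version, per-flag
#' counts) into `outDir`. All computation happens before any file is
#' written, so a failure leaves no partial outputs.
#'
#' @param rrsPath path to a `GLORIA_Rrs.csv`-shaped file.
#' @param outDir output directory (created if needed).
#' @param suspectFrom optional path to an existing flag file whose
#'   `Suspect` column (expert elicitation; never computed) is carried over
#'   by `GLORIA_ID`.
#' @param verbose log per-flag counts.
#' @return Invisibly, the [runQC()] result list plus the manifest.
#' @export
qcPipeline <- function(rrsPath, outDir, suspectFrom = NULL, verbose = TRUE) {
  spectra <- readSpectralTable(rrsPath, "Rrs")
  suspect <- NULL
  if (!is.null(suspectFrom)) {
    sf <- readFlags(suspectFrom)
    if (!"Suspect" %in% names(sf)) {
      stop("'", suspectFrom, "' has no Suspect column")
    }
    suspect <- setNames(sf$Suspect, sf$GLORIA_ID)
  }
  qc <- runQC(spectra, suspect = suspect, verbose = verbose)
  if (nrow(qc$flags) == 0L) stop("input table contains no spectra")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeFlags(qc$flags, file.path(outDir, "GLORIA_qc_flags.csv"))
  writeAncillary(qc$ancillary, file.path(outDir, "GLORIA_qc_ancillary.csv"))
  counts <- colSums(qc$flags[.FLAG_COLUMNS] == 1L, na.rm = TRUE)
  manifest <- .write_manifest(
    outDir, inputs = c(list(rrs = rrsPath),
                       if (!is.null(suspectFrom)) list(suspect = suspectFrom)),
    counts = counts, extra = list(n_spectra = nrow(qc$flags)))
  invisible(c(qc, list(manifest = manifest)))
}

#' File-to-file synthetic dataset generation
#'
#' Generates a labelled synthetic dataset and writes it in the GLORIA
#' layout: `GLORIA_Rrs.csv`, `GLORIA_meta_and_lab.csv`, the ground-truth
#' tables (`ground_truth_flags.csv`, `ground_truth_wq_outliers.csv`) and a
#' manifest. Configuration is a [syntheticConfig()] or a YAML file of
#' key-value pairs overriding its defaults.
#'
#' @param config a [syntheticConfig()], or a path to a YAML file.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the [generateDataset()] result.
#' @export
simulatePipeline <- function(config = syntheticConfig(), outDir) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    opts <- yaml::read_yaml(config)
    known <- names(formals(syntheticConfig))
    unknown <- setdiff(names(opts), known)
    if (length(unknown)) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    if (!is.null(opts$artifactWeights)) {
      opts$artifactWeights <- unlist(opts$artifactWeights)
    }
    config <- do.call(syntheticConfig, opts)
  }
  d <- generateDataset(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSpectralTable(d$spectra, file.path(outDir, "GLORIA_Rrs.csv"))
  write.csv(d$meta, file.path(outDir, "GLORIA_meta_and_lab.csv"),
            row.names = FALSE, quote = FALSE, na = "", fileEncoding = "UTF-8")
  write.csv(d$truth$flags, file.path(outDir, "ground_truth_flags.csv"),
            row.names = FALSE, quote = FALSE, na = "", fileEncoding = "UTF-8")
  write.csv(d$truth$wq, file.path(outDir, "ground_truth_wq_outliers.csv"),
            row.names = FALSE, quote = FALSE, na = "", fileEncoding = "UTF-8")
  .write_manifest(outDir, inputs = list(),
                  extra = list(n_spectra = ncol(d$spectra),
                               seed = d$config$seed))
  invisible(d)
}

#' File-to-file water-quality outlier screen
#'
#' Reads the metadata/lab table, runs [screenOutliers()], writes
#' `wq_outlier_report.csv` and a manifest, and logs flagged counts per
#' water type.
#'
#' @param metaPath path to a `GLORIA_meta_and_lab.csv`-shaped file.
#' @param outDir output directory (created if needed).
#' @param k threshold in standard deviations.
#' @param verbose log flagged counts per water type.
#' @return Invisibly, the outlier report data.frame.
#' @export
screenPipeline <- function(metaPath, outDir, k = 3, verbose = TRUE) {
  meta <- readMetadata(metaPath)
  if (!"Water_type" %in% names(meta)) {
    stop("metadata has no 'Water_type' column")
  }
  report <- screenOutliers(meta, k = k)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeOutlierReport(report, file.path(outDir, "wq_outlier_report.csv"))
  if (verbose) {
    flagged <- report[!is.na(report$flag) & report$flag == 1L, ]
    message("water-quality outliers flagged (k = ", k, "): ", nrow(flagged))
    if (nrow(flagged)) {
      tab <- table(flagged$water_type)
      for (nm in names(tab)) message(sprintf("  %-28s %d", nm, tab[[nm]]))
    }
  }
  .write_manifest(outDir, inputs = list(meta = metaPath),
                  extra = list(n_records = nrow(meta), k = k))
  invisible(report)
}
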