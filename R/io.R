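#' @include qc-flags.R
NULL

# Canonical numeric metadata columns and their validation bounds.
.META_NUMERIC <- c("Chla", "Chl_plus_phaeo", "TSS", "aCDOM_440",
                   "Secchi_depth", "Latitude", "Longitude",
                   "Phaeophytin_correction", "Measurement_method",
                   "Spectral_resolution_nm")
.WQ_VARIABLES <- c(Chla = "chla", TSS = "tss", aCDOM_440 = "acdom440",
                   Secchi_depth = "secchi")

#' Read one spectral table in the GLORIA CSV layout
#'
#' Parses a file shaped like `GLORIA_Rrs.csv` and siblings: an ID column
#' (`GLORIA_ID`) followed by one column per wavelength named
#' `<prefix>_<nm>` (e.g. `Rrs_350`, ..., `Rrs_900`). The wavelength is
#' parsed from the suffix after the last underscore; files may span any
#' sub-range of 350--900 nm. Empty cells become `NA`; sample order is
#' preserved. Columns are reordered to ascending wavelength if needed.
#'
#' @param path CSV file path (comma-separated, UTF-8, "." decimal, empty
#'   string = missing).
#' @param quantity radiometric quantity stored in the file.
#' @return A \linkS4class{SpectraSet}.
#' @export
readSpectralTable <- function(path, quantity = c("Rrs", "Es", "Lw", "Lt",
                                                 "Lsky", "Lu")) {
  quantity <- match.arg(quantity)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                 fileEncoding = "UTF-8")
  if (ncol(df) < 1L) stop("schema error: file has no columns")
  header <- names(df)
  if (header[1L] != "GLORIA_ID") {
    stop("schema error: first column must be 'GLORIA_ID', found '",
         header[1L], "'")
  }
  speccols <- header[-1L]
  wl <- suppressWarnings(as.integer(sub(".*_", "", speccols)))
  bad <- which(is.na(wl) | !grepl("_", speccols))
  if (length(bad)) {
    stop("schema error: column '", speccols[bad[1L]],
         "' does not end in a wavelength suffix")
  }
  if (anyDuplicated(wl)) {
    stop("schema error: duplicate wavelength column '",
         speccols[which(duplicated(wl))[1L]], "'")
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("validation error: duplicate GLORIA_ID '",
         ids[which(duplicated(ids))[1L]], "'")
  }
  m <- as.matrix(df[-1L])
  suppressWarnings(storage.mode(m) <- "double")
  ord <- order(wl)
  SpectraSet(t(m[, ord, drop = FALSE]), wl[ord], ids, quantity)
}

#' Write a SpectraSet in the GLORIA CSV layout
#'
#' One row per sample; columns `GLORIA_ID`, then `<quantity>_<nm>` in
#' ascending wavelength. Values are printed with up to 10 significant
#' digits so write/read round trips are lossless at single-precision
#' source accuracy; `NA` becomes an empty cell.
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
writeSpectralTable <- function(x, path) {
  stopifnot(is(x, "SpectraSet"))
  m <- t(spectraMatrix(x))
  fmt <- matrix("", nrow = nrow(m), ncol = ncol(m))
  fin <- is.finite(m)
  fmt[fin] <- formatC(m[fin], digits = 10, format = "g")
  df <- data.frame(GLORIA_ID = sampleIDs(x), fmt, check.names = FALSE)
  names(df) <- c("GLORIA_ID", paste0(quantity(x), "_", wavelengths(x)))
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read the ancillary / water-quality metadata table
#'
#' Reads `GLORIA_meta_and_lab.csv`: one row per sample with water-quality
#' measurements (`Chla` mg m-3, `TSS` g m-3, `aCDOM_440` m-1,
#' `Secchi_depth` m), categorical descriptors (`Water_type`,
#' `Water_body_type`), position, timestamps and method identifiers.
#' Known numeric columns are coerced and validated (latitude within
#' +/-90, longitude within +/-180, concentrations non-negative,
#' `Phaeophytin_correction` 0/1); unknown columns are retained untouched
#' so the full column inventory of the distribution is carried opaquely.
#'
#' @param path CSV file path.
#' @return data.frame, one row per sample, `GLORIA_ID` first.
#' @export
readMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                 fileEncoding = "UTF-8")
  if (!"GLORIA_ID" %in% names(df)) {
    stop("schema error: column 'GLORIA_ID' is required")
  }
  for (col in intersect(.META_NUMERIC, names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  .validate_metadata(df)
  df
}

.validate_metadata <- function(df) {
  chk <- function(col, test, what) {
    if (col %in% names(df)) {
      v <- df[[col]]
      bad <- which(!is.na(v) & !test(v))
      if (length(bad)) {
        stop(sprintf("validation error: %s (row %d, %s = %g)",
                     what, bad[1L], col, v[bad[1L]]))
      }
    }
  }
  chk("Latitude", function(v) v >= -90 & v <= 90, "latitude outside [-90, 90]")
  chk("Longitude", function(v) v >= -180 & v <= 180,
      "longitude outside [-180, 180]")
  for (col in c("Chla", "Chl_plus_phaeo", "TSS", "aCDOM_440", "Secchi_depth")) {
    chk(col, function(v) v >= 0, paste0("negative ", col))
  }
  chk("Phaeophytin_correction", function(v) v %in% c(0, 1),
      "Phaeophytin_correction must be 0 or 1")
  invisible(df)
}

#' Write (or read back) a quality-flag table
#'
#' Writes the per-sample tri-state flags as distributed: columns
#' `GLORIA_ID`, the seven component flags in distribution order, and the
#' aggregate `Flagged`. Undeterminable flags (`NA`) become empty cells,
#' signalling that the spectrum did not include the required wavelength
#' range.
#'
#' @param flags data.frame as returned in `runQC(x)$flags`.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
writeFlags <- function(flags, path) {
  if (nrow(flags) == 0L) stop("no QC results to write")
  need <- c("GLORIA_ID", .FLAG_COLUMNS)
  missing_cols <- setdiff(need, names(flags))
  if (length(missing_cols)) {
    stop("flag table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  write.csv(flags[need], path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFlags
#' @export
readFlags <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE, na.strings = c("", "NA"),
                 fileEncoding = "UTF-8")
  if (!"GLORIA_ID" %in% names(df)) {
    stop("schema error: column 'GLORIA_ID' is required")
  }
  for (col in intersect(.FLAG_COLUMNS, names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Write the ancillary QC metric table
#'
#' Distribution layout: `GLORIA_ID`, `Oxygen_peak_height`,
#' `Apparent_visible_wavelength`, `QWIP_score` (the NDI column computed by
#' [runQC()] is an intermediate and is not part of the distributed file).
#'
#' @param ancillary data.frame as returned in `runQC(x)$ancillary`.
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
writeAncillary <- function(ancillary, path) {
  need <- c("GLORIA_ID", "Oxygen_peak_height", "Apparent_visible_wavelength",
            "QWIP_score")
  missing_cols <- setdiff(need, names(ancillary))
  if (length(missing_cols)) {
    stop("ancillary table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- ancillary[need]
  for (col in need[-1L]) out[[col]] <- signif(out[[col]], 10)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}
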