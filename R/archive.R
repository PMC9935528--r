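#' @include pipeline.R
NULL

#' Recompute headline statistics of a downloaded archive distribution
#'
#' Given a local directory holding the distributed archive files
#' (`GLORIA_Rrs.csv`, `GLORIA_meta_and_lab.csv`, optionally `GLORIA_Lt.csv`,
#' `GLORIA_Lsky.csv`, `GLORIA_Es.csv` and `GLORIA_qc_flags.csv`), this
#' recomputes the dataset cardinalities (number of spectra, distinct water
#' bodies, share of lakes, number of samples with complete above-water
#' radiometry plus time and location) and reruns the full flag suite,
#' comparing the per-flag counts against the distributed flag file when it
#' is present. The archive itself is large and must be downloaded by the
#' user; nothing is bundled.
#'
#' @param dir directory containing the distribution CSVs.
#' @param waterBodyColumn metadata column identifying the water body
#'   (auto-detected among common spellings when `NULL`).
#' @param datetimeColumn metadata column with the observation timestamp
#'   (auto-detected when `NULL`).
#' @return List: `n_spectra`, `n_water_bodies`, `pct_lakes`,
#'   `n_above_water_complete`, `flag_counts` (recomputed, including the
#'   distributed Suspect column when available), `distributed_flag_counts`
#'   (from the shipped flag file, or `NULL`), and `discrepancies`
#'   (per-flag recomputed minus distributed).
#' @export
validateArchive <- function(dir, waterBodyColumn = NULL,
                            datetimeColumn = NULL) {
  rrs_path <- file.path(dir, "GLORIA_Rrs.csv")
  meta_path <- file.path(dir, "GLORIA_meta_and_lab.csv")
  if (!file.exists(rrs_path) || !file.exists(meta_path)) {
    stop("archive distribution not found under '", dir,
         "': expected GLORIA_Rrs.csv and GLORIA_meta_and_lab.csv")
  }
  spectra <- readSpectralTable(rrs_path, "Rrs")
  meta <- readMetadata(meta_path)

  pick <- function(given, candidates, pattern) {
    if (!is.null(given)) return(intersect(given, names(meta))[1])
    hit <- intersect(candidates, names(meta))
    if (length(hit)) return(hit[1])
    hit <- grep(pattern, names(meta), ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  wb_col <- pick(waterBodyColumn,
                 c("Water_body_name", "Site_name", "Water_body"),
                 "water.?body|site")
  dt_col <- pick(datetimeColumn, c("Date_Time", "Datetime", "Date_time_UTC"),
                 "date|time")

  n_spectra <- length(sampleIDs(spectra))
  n_water_bodies <- if (!is.na(wb_col)) {
    length(unique(stats::na.omit(meta[[wb_col]])))
  } else NA_integer_
  pct_lakes <- if ("Water_body_type" %in% names(meta)) {
    100 * mean(grepl("lake", meta$Water_body_type, ignore.case = TRUE),
               na.rm = TRUE)
  } else NA_real_

  has_rows <- function(fname) {
    p <- file.path(dir, fname)
    if (!file.exists(p)) return(character(0))
    tbl <- readSpectralTable(p, sub("GLORIA_(.*)\\.csv", "\\1", fname))
    keep <- colSums(!is.na(spectraMatrix(tbl))) > 0
    sampleIDs(tbl)[keep]
  }
  ids_lt <- has_rows("GLORIA_Lt.csv")
  ids_lsky <- has_rows("GLORIA_Lsky.csv")
  ids_es <- has_rows("GLORIA_Es.csv")
  loc_ok <- meta$GLORIA_ID[!is.na(meta$Latitude) & !is.na(meta$Longitude) &
                           (if (!is.na(dt_col)) !is.na(meta[[dt_col]]) else TRUE)]
  n_complete <- length(Reduce(intersect,
                              list(ids_lt, ids_lsky, ids_es, loc_ok)))

  flags_path <- file.path(dir, "GLORIA_qc_flags.csv")
  suspect <- NULL
  distributed <- NULL
  if (file.exists(flags_path)) {
    shipped <- readFlags(flags_path)
    if ("Suspect" %in% names(shipped)) {
      suspect <- setNames(shipped$Suspect, shipped$GLORIA_ID)
    }
    distributed <- colSums(shipped[intersect(.FLAG_COLUMNS, names(shipped))] == 1L,
                           na.rm = TRUE)
    storage.mode(distributed) <- "integer"
  }
  qc <- runQC(spectra, suspect = suspect)
  counts <- colSums(qc$flags[.FLAG_COLUMNS] == 1L, na.rm = TRUE)
  storage.mode(counts) <- "integer"

  list(
    n_spectra = n_spectra,
    n_water_bodies = n_water_bodies,
    pct_lakes = pct_lakes,
    n_above_water_complete = n_complete,
    flag_counts = counts,
    distributed_flag_counts = distributed,
    discrepancies = if (!is.null(distributed)) {
      counts[names(distributed)] - distributed
    } else NULL
  )
}
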