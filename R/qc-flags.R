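#' @include metrics.R
NULL

# Flag column order used in the distributed flag file.
.FLAG_COLUMNS <- c("Noisy_red", "Noisy_blue", "Baseline_shift",
                   "Oxygen_signal", "Negative_uv_slope", "QWIP_fail",
                   "Suspect", "Flagged")

# Procedural flags: computable from the spectrum alone (Suspect comes from
# expert elicitation and is only ever read in, never computed; QWIP_fail is
# the statistical test and is computed separately).
.PROCEDURAL_FLAGS <- c("Noisy_red", "Noisy_blue", "Baseline_shift",
                       "Oxygen_signal", "Negative_uv_slope")

# Shared skeleton of the standardize-then-fit noise flags. All thresholds
# are strict inequalities, exactly as distributed.
.noise_flag <- function(wl, values, lo, hi, degree, threshold) {
  .check_spectrum(wl, values)
  if (!.covered(wl, values, lo, hi)) return(NA_integer_)
  z <- tryCatch(standardizeSpectrum(wl, values), error = function(e) NULL)
  if (is.null(z)) return(NA_integer_)
  f <- fitWindow(wl, z, c(lo, hi), degree)
  as.integer(f$rmse > threshold)
}

#' Red-end noise flag
#'
#' High-frequency variability near the red end, a signature of instrument
#' noise: the spectrum is standardized to zero mean and unit standard
#' deviation, a 4th-order polynomial is fitted over 750--900 nm, and the
#' spectrum is flagged when the fit RMSE exceeds 0.2.
#'
#' @inheritParams resampleSpectrum
#' @return `1L` flagged, `0L` clean, `NA` when 750--900 nm is not fully
#'   covered or the spectrum has zero variance.
#' @export
flagNoisyRed <- function(wl, values) {
  .noise_flag(wl, values, 750L, 900L, 4L, 0.2)
}

#' Blue-end noise flag
#'
#' As [flagNoisyRed()] with window 350--400 nm and RMSE threshold 0.15.
#'
#' @inheritParams resampleSpectrum
#' @return Tri-state flag as in [flagNoisyRed()].
#' @export
flagNoisyBlue <- function(wl, values) {
  .noise_flag(wl, values, 350L, 400L, 4L, 0.15)
}

#' Baseline shift flag
#'
#' Operates on the raw reflectance in sr-1 (not standardized; the slope
#' threshold below carries sr-1 nm-1 units). Two failure modes:
#' \itemize{
#'   \item \emph{Shifted up}: the minimum reflectance exceeds 60\% of the
#'     spectrum median (computed over the full non-missing extent; the
#'     whole spectrum floats high, as after under-subtraction of glint).
#'   \item \emph{Shifted down}: at least 20 negative values over the full
#'     extent, and either (a) a linear slope over 765--900 nm below
#'     -8.75e-7 sr-1 nm-1 together with more than 50\% negative values in
#'     that window, or (b) more than 70\% negative values in 765--900 nm,
#'     or (c) at least 20 negative values within 350--450 nm.
#' }
#' The flag is `NA` only when neither branch is determinable: the median is
#' non-positive (up-shift test meaningless) and no down-shift branch has
#' its window covered.
#'
#' @inheritParams resampleSpectrum
#' @return Tri-state flag.
#' @export
flagBaselineShift <- function(wl, values) {
  .check_spectrum(wl, values)
  ok <- !is.na(values)
  if (!any(ok)) return(NA_integer_)
  med <- median(values[ok])

  up <- NA_integer_
  if (is.finite(med) && med > 0) {
    up <- as.integer(min(values[ok]) / med > 0.6)
  }

  n_neg_total <- sum(values[ok] < 0)
  nir_cov <- .covered(wl, values, 765L, 900L)
  uvb_cov <- .covered(wl, values, 350L, 450L)
  down <- NA_integer_
  if (nir_cov || uvb_cov) {
    if (n_neg_total < 20L) {
      down <- 0L
    } else {
      hit <- FALSE
      if (nir_cov) {
        idx <- .window_idx(wl, 765, 900)
        frac_neg <- mean(values[idx] < 0)
        slope <- fitWindow(wl, values, c(765, 900), 1L)$slope
        hit <- hit || (slope < -8.75e-7 && frac_neg > 0.5) || frac_neg > 0.7
      }
      if (uvb_cov) {
        idx <- .window_idx(wl, 350, 450)
        hit <- hit || sum(values[idx] < 0) >= 20L
      }
      down <- as.integer(hit)
    }
  }

  if (identical(up, 1L) || identical(down, 1L)) return(1L)
  if (is.na(up) && is.na(down)) return(NA_integer_)
  0L
}

#' Oxygen A-band flag
#'
#' Flags spectra whose [oxygenPeakHeight()] exceeds 0.1 (standardized
#' units), indicating a residual atmospheric oxygen absorption feature
#' near 762 nm from sensor intercalibration issues.
#'
#' @inheritParams oxygenPeakHeight
#' @return Tri-state flag; `NA` when 745--785 nm is not fully covered or
#'   the spectrum has zero variance.
#' @export
flagOxygen <- function(wl, values, searchWindow = c(759, 766)) {
  h <- oxygenPeakHeight(wl, values, searchWindow)
  if (is.na(h)) return(NA_integer_)
  as.integer(h > 0.1)
}

#' Negative ultraviolet-blue slope flag
#'
#' The spectrum is standardized to zero mean and unit standard deviation
#' and a straight line is fitted over 350--420 nm; slopes below -0.005
#' (standardized units per nm) are flagged. Such slopes typically result
#' from suboptimal diffuse sky radiance correction.
#'
#' @inheritParams resampleSpectrum
#' @return Tri-state flag.
#' @export
flagNegativeUvSlope <- function(wl, values) {
  .check_spectrum(wl, values)
  if (!.covered(wl, values, 350L, 420L)) return(NA_integer_)
  z <- tryCatch(standardizeSpectrum(wl, values), error = function(e) NULL)
  if (is.null(z)) return(NA_integer_)
  f <- fitWindow(wl, z, c(350, 420), 1L)
  as.integer(f$slope < -0.005)
}

#' QWIP failure flag
#'
#' Flags spectra whose absolute [qwipScore()] exceeds 0.2 (strict
#' inequality), i.e. whose NDI deviates from the value the QWIP polynomial
#' predicts at their apparent visible wavelength.
#'
#' @inheritParams qwipScore
#' @return Tri-state flag; `NA` when AVW or NDI is undefined (visible
#'   range or the 492/665 nm bands not covered).
#' @export
flagQwip <- function(wl, values, coeffs = qwipCoefficients()) {
  s <- qwipScore(wl, values, coeffs)
  if (is.na(s)) return(NA_integer_)
  as.integer(abs(s) > 0.2)
}

#' Aggregate component flags into the overall Flagged bit
#'
#' `Flagged` is 1 when any component flag (including the externally
#' supplied Suspect flag) is 1; 0 when no component is 1 and at least one
#' is determinable; `NA` only when every component is `NA`.
#'
#' @param ... tri-state component flags (integers 0/1/NA), individually or
#'   as vectors.
#' @return Tri-state aggregate.
#' @examples
#' aggregateFlags(0L, NA, 0L)  # 0: NA does not assert presence
#' aggregateFlags(0L, 1L)      # 1
#' @export
aggregateFlags <- function(...) {
  comp <- unlist(list(...), use.names = FALSE)
  if (length(comp) == 0L || all(is.na(comp))) return(NA_integer_)
  as.integer(any(comp == 1L, na.rm = TRUE))
}

.qc_one <- function(wl, values) {
  flags <- c(
    Noisy_red = flagNoisyRed(wl, values),
    Noisy_blue = flagNoisyBlue(wl, values),
    Baseline_shift = flagBaselineShift(wl, values),
    Oxygen_signal = flagOxygen(wl, values),
    Negative_uv_slope = flagNegativeUvSlope(wl, values),
    QWIP_fail = flagQwip(wl, values)
  )
  anc <- c(
    Oxygen_peak_height = oxygenPeakHeight(wl, values),
    Apparent_visible_wavelength = avw(wl, values),
    NDI = ndi(wl, values),
    QWIP_score = qwipScore(wl, values)
  )
  list(flags = flags, ancillary = anc)
}

#' Quality control of a reflectance table
#'
#' Applies every quality flag and ancillary metric to each spectrum of a
#' reflectance \linkS4class{SpectraSet} and aggregates them into the
#' distributed flag-table layout. The `Suspect` flag comes from expert
#' elicitation and is accepted as an input, never computed; it defaults to
#' `NA` for every spectrum.
#'
#' @param x a \linkS4class{SpectraSet} with `quantity == "Rrs"`.
#' @param suspect optional named tri-state vector (names = sample IDs) or
#'   unnamed vector of length `ncol(x)` supplying the Suspect flag.
#' @param verbose log per-flag counts to the console.
#' @param ... unused.
#' @return List with two data.frames: `flags` (columns `GLORIA_ID`, the
#'   seven component flags in distribution order, `Flagged`) and
#'   `ancillary` (columns `GLORIA_ID`, `Oxygen_peak_height`,
#'   `Apparent_visible_wavelength`, `NDI`, `QWIP_score`).
#' @examples
#' set.seed(1)
#' d <- generateDataset(syntheticConfig(nSamples = 5))
#' qc <- runQC(d$spectra)
#' qc$flags
#' @export
setMethod("runQC", "SpectraSet", function(x, suspect = NULL, verbose = FALSE, ...) {
  if (quantity(x) != "Rrs") {
    stop("runQC requires a SpectraSet of quantity 'Rrs', got '", quantity(x), "'")
  }
  ids <- sampleIDs(x)
  n <- length(ids)
  wl <- wavelengths(x)
  m <- spectraMatrix(x)

  if (is.null(suspect)) {
    suspect <- rep(NA_integer_, n)
  } else if (!is.null(names(suspect))) {
    suspect <- as.integer(suspect)[match(ids, names(suspect))]
  } else if (length(suspect) == n) {
    suspect <- as.integer(suspect)
  } else {
    stop("'suspect' must be named by sample ID or have one entry per spectrum")
  }

  fm <- matrix(NA_integer_, nrow = n, ncol = 6L,
               dimnames = list(NULL, setdiff(.FLAG_COLUMNS,
                                             c("Suspect", "Flagged"))))
  am <- matrix(NA_real_, nrow = n, ncol = 4L,
               dimnames = list(NULL, c("Oxygen_peak_height",
                                       "Apparent_visible_wavelength",
                                       "NDI", "QWIP_score")))
  for (j in seq_len(n)) {
    r <- .qc_one(wl, m[, j])
    fm[j, ] <- r$flags
    am[j, ] <- r$ancillary
  }
  flagged <- vapply(seq_len(n), function(j) {
    aggregateFlags(fm[j, ], suspect[j])
  }, integer(1))

  flags <- data.frame(GLORIA_ID = ids, fm, Suspect = suspect,
                      Flagged = flagged, check.names = FALSE)
  ancillary <- data.frame(GLORIA_ID = ids, am, check.names = FALSE)

  if (verbose) {
    counts <- colSums(flags[.FLAG_COLUMNS] == 1L, na.rm = TRUE)
    message("QC flag counts over ", n, " spectra:")
    for (nm in .FLAG_COLUMNS) {
      message(sprintf("  %-18s %d", nm, counts[[nm]]))
    }
  }
  list(flags = flags, ancillary = ancillary)
})
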