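#' @include spectra-ops.R
NULL

#' QWIP polynomial coefficients
#'
#' Coefficients of the 4th-order Quality Water Index Polynomial relating
#' apparent visible wavelength (nm) to the predicted normalized difference
#' index, in decreasing powers of AVW. Transcribed verbatim from Dierssen
#' et al. (2022) "QWIP: A Quantitative Metric for Quality Screening of
#' In-Water Radiometric Data", Frontiers in Remote Sensing 3:869611.
#'
#' @return Numeric vector of length 5 (coefficients of AVW^4 .. AVW^0).
#' @export
qwipCoefficients <- function() {
  c(-8.399885e-9, 1.715532e-5, -1.301670e-2, 4.357838e0, -5.449532e2)
}

.polyval <- function(p, x) {
  acc <- 0
  for (c in p) acc <- acc * x + c
  acc
}

#' Oxygen A-band peak height
#'
#' Detects the imprint of atmospheric oxygen absorption near 762 nm (a sign
#' of sensor intercalibration problems between the radiance and irradiance
#' channels). The spectrum is standardized over its full extent; a straight
#' baseline is drawn between anchor points at 750 and 780 nm whose
#' ordinates are the medians of the standardized values over 745--755 nm
#' and 775--785 nm; the height is the maximum absolute deviation of the
#' standardized spectrum from that baseline inside the search window
#' (759--766 nm by default, bracketing the A-band while excluding the
#' anchor windows). Local maxima and minima count equally.
#'
#' @inheritParams resampleSpectrum
#' @param searchWindow length-2 inclusive wavelength bounds of the search
#'   for the extreme residual.
#' @return Non-negative height in standardized units, or `NA` if 745--785
#'   nm is not fully covered or the spectrum has zero variance.
#' @export
oxygenPeakHeight <- function(wl, values, searchWindow = c(759, 766)) {
  .check_spectrum(wl, values)
  if (!.covered(wl, values, 745L, 785L)) return(NA_real_)
  z <- tryCatch(standardizeSpectrum(wl, values), error = function(e) NULL)
  if (is.null(z)) return(NA_real_)
  m1 <- median(z[.window_idx(wl, 745, 755)])
  m2 <- median(z[.window_idx(wl, 775, 785)])
  slope <- (m2 - m1) / (780 - 750)
  idx <- .window_idx(wl, searchWindow[1], searchWindow[2])
  baseline <- m1 + slope * (wl[idx] - 750)
  max(abs(z[idx] - baseline))
}

#' Apparent visible wavelength (AVW)
#'
#' The weighted harmonic mean of the visible wavelengths with reflectance
#' as weights, a one-number descriptor of spectral shape:
#' \deqn{AVW = \sum_{400}^{700} R_{rs}(\lambda) \big/
#'       \sum_{400}^{700} R_{rs}(\lambda)/\lambda}
#' computed as discrete sums on the 1 nm grid, 400--700 nm inclusive.
#' Invariant to positive scaling of the spectrum.
#'
#' @inheritParams resampleSpectrum
#' @return AVW in nm, or `NA` if 400--700 nm is not fully covered or the
#'   denominator is non-positive.
#' @export
avw <- function(wl, values) {
  .check_spectrum(wl, values)
  if (!.covered(wl, values, 400L, 700L)) return(NA_real_)
  idx <- .window_idx(wl, 400, 700)
  denom <- sum(values[idx] / wl[idx])
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  sum(values[idx]) / denom
}

#' Normalized difference index (NDI) at 492 and 665 nm
#'
#' \deqn{NDI = (R_{rs}(665) - R_{rs}(492)) / (R_{rs}(665) + R_{rs}(492))}
#' with band values read at the exact integer grid wavelengths.
#'
#' @inheritParams resampleSpectrum
#' @param bands the two wavelengths (blue-green, red), defaults 492/665 nm.
#' @return NDI (unitless), `NA` if either band is missing or the
#'   denominator is zero.
#' @export
ndi <- function(wl, values, bands = c(492L, 665L)) {
  .check_spectrum(wl, values)
  i1 <- match(bands[1], wl)
  i2 <- match(bands[2], wl)
  if (is.na(i1) || is.na(i2)) return(NA_real_)
  a <- values[i2]
  b <- values[i1]
  if (is.na(a) || is.na(b) || (a + b) == 0) return(NA_real_)
  (a - b) / (a + b)
}

#' QWIP score
#'
#' Difference between the observed NDI and the NDI predicted from the
#' spectrum's apparent visible wavelength by the 4th-order QWIP polynomial.
#' Spectra from optically deep natural waters cluster tightly around the
#' polynomial; large absolute scores indicate atypical spectral shapes.
#'
#' @inheritParams resampleSpectrum
#' @param coeffs polynomial coefficients in decreasing powers of AVW;
#'   defaults to [qwipCoefficients()].
#' @return Unitless score, `NA` when AVW or NDI is undefined.
#' @export
qwipScore <- function(wl, values, coeffs = qwipCoefficients()) {
  a <- avw(wl, values)
  n <- ndi(wl, values)
  if (is.na(a) || is.na(n)) return(NA_real_)
  n - .polyval(coeffs, a)
}

# CIE 1931 2-degree colour-matching functions via the multi-lobe piecewise
# Gaussian analytic fit of Wyman, Sloan & Shirley (2013), "Simple Analytic
# Approximations to the CIE XYZ Color Matching Functions", JCGT 2(2):1-11.
.cmf_lobe <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 2-degree colour-matching functions
#'
#' Evaluates the x-bar, y-bar, z-bar observer functions on an arbitrary
#' wavelength grid using the published multi-lobe piecewise-Gaussian
#' analytic representation (Wyman, Sloan & Shirley 2013, JCGT).
#'
#' @param wl wavelengths in nm.
#' @return data.frame with columns `wavelength_nm`, `xbar`, `ybar`, `zbar`.
#' @export
cieCMF <- function(wl) {
  data.frame(
    wavelength_nm = wl,
    xbar = 1.056 * .cmf_lobe(wl, 599.8, 37.9, 31.0) +
           0.362 * .cmf_lobe(wl, 442.0, 16.0, 26.7) -
           0.065 * .cmf_lobe(wl, 501.1, 20.4, 26.2),
    ybar = 0.821 * .cmf_lobe(wl, 568.8, 46.9, 40.5) +
           0.286 * .cmf_lobe(wl, 530.9, 16.3, 31.1),
    zbar = 1.217 * .cmf_lobe(wl, 437.0, 11.8, 36.0) +
           0.681 * .cmf_lobe(wl, 459.0, 26.0, 13.8)
  )
}

#' CIE chromaticity of a reflectance spectrum
#'
#' Tristimulus values are computed by discrete integration of the spectrum
#' against the CIE 1931 2-degree colour-matching functions over 400--700 nm
#' with equal-energy normalization (each observer function scaled to unit
#' sum over the window, so a spectrally flat spectrum maps exactly to the
#' equal-energy white point). Chromaticity `x = X/(X+Y+Z)`,
#' `y = Y/(X+Y+Z)`; the hue angle is measured counter-clockwise from the
#' positive x-axis at the white point (1/3, 1/3), in degrees `[0, 360)`.
#'
#' @inheritParams resampleSpectrum
#' @return List with elements `x`, `y`, `hue_angle`, or `NA` components if
#'   400--700 nm is not fully covered or `X + Y + Z <= 0`.
#' @export
chromaticity <- function(wl, values) {
  .check_spectrum(wl, values)
  if (!.covered(wl, values, 400L, 700L)) {
    return(list(x = NA_real_, y = NA_real_, hue_angle = NA_real_))
  }
  idx <- .window_idx(wl, 400, 700)
  cmf <- cieCMF(wl[idx])
  xb <- cmf$xbar / sum(cmf$xbar)
  yb <- cmf$ybar / sum(cmf$ybar)
  zb <- cmf$zbar / sum(cmf$zbar)
  X <- sum(values[idx] * xb)
  Y <- sum(values[idx] * yb)
  Z <- sum(values[idx] * zb)
  tot <- X + Y + Z
  if (!is.finite(tot) || tot <= 0) {
    return(list(x = NA_real_, y = NA_real_, hue_angle = NA_real_))
  }
  x <- X / tot
  y <- Y / tot
  ang <- atan2(y - 1 / 3, x - 1 / 3) * 180 / pi
  if (!is.na(ang) && ang < 0) ang <- ang + 360
  list(x = x, y = y, hue_angle = ang)
}

#' Assign an optical water type by nearest centroid
#'
#' Classifies a reflectance spectrum against a user-supplied set of optical
#' water type centroid spectra (for example the 13 inland/coastal types of
#' Spyrakos et al. 2018). Spectra and centroids are restricted to their
#' common wavelength range, area-normalized (divided by their sum), and
#' compared with the chosen similarity; ties go to the lowest class index.
#'
#' @inheritParams resampleSpectrum
#' @param centroids numeric matrix of centroid spectra, wavelengths in rows
#'   (rownames = nm), one column per class (colnames = class IDs).
#' @param method similarity: `"spectral-angle"` (default; scale-invariant),
#'   `"euclidean"` (on area-normalized spectra), or `"correlation"`.
#' @return Class ID (column name, or index if unnamed) of the nearest
#'   centroid.
#' @export
assignOWT <- function(wl, values, centroids,
                      method = c("spectral-angle", "euclidean", "correlation")) {
  method <- match.arg(method)
  .check_spectrum(wl, values)
  if (is.null(dim(centroids)) || ncol(centroids) < 1L) {
    stop("at least one centroid spectrum is required")
  }
  cw <- as.integer(rownames(centroids))
  if (anyNA(cw)) stop("centroid rownames must be wavelengths in nm")
  common <- intersect(wl, cw)
  if (length(common) < 3L) stop("spectrum and centroids share too few wavelengths")
  v <- values[match(common, wl)]
  if (anyNA(v)) stop("spectrum has missing values on the centroid grid")
  cm <- centroids[match(common, cw), , drop = FALSE]
  v <- v / sum(v)
  cm <- sweep(cm, 2L, colSums(cm), "/")
  d <- switch(method,
    "spectral-angle" = {
      num <- as.numeric(crossprod(cm, v))
      cosang <- num / (sqrt(colSums(cm^2)) * sqrt(sum(v^2)))
      acos(pmin(pmax(cosang, -1), 1))
    },
    "euclidean" = sqrt(colSums((cm - v)^2)),
    "correlation" = 1 - as.numeric(cor(v, cm))
  )
  k <- which.min(d)  # which.min takes the first (lowest) index on ties
  if (!is.null(colnames(centroids))) colnames(centroids)[k] else k
}
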