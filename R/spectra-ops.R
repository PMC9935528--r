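#' @include SpectraSet-class.R
NULL

# All per-spectrum computations work on a pair (wl, values): an integer
# wavelength grid and the corresponding numeric values, NA = missing.
# SpectraSet methods loop over columns of the assay matrix.

.check_spectrum <- function(wl, values) {
  if (length(wl) != length(values)) {
    stop("wavelength grid and values must have equal length")
  }
  if (length(wl) > 1L && any(diff(wl) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  invisible(NULL)
}

# TRUE when every integer wavelength lo..hi is on the grid with a
# non-missing value ("full-window coverage"); flags return NA otherwise.
.covered <- function(wl, values, lo, hi) {
  need <- lo:hi
  idx <- match(need, wl)
  !anyNA(idx) && !anyNA(values[idx])
}

.window_idx <- function(wl, lo, hi) which(wl >= lo & wl <= hi)

#' Linearly resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation between native grid points; requested wavelengths
#' outside the native range become `NA` (no extrapolation, so downstream
#' flags can report insufficient coverage rather than invented data).
#'
#' @param wl integer wavelengths (nm) of the input, strictly increasing.
#' @param values numeric values, `NA` = missing.
#' @param grid wavelengths to resample onto.
#' @return Numeric vector over `grid`, named by wavelength.
#' @examples
#' resampleSpectrum(c(400, 402), c(1, 3), 401)  # midpoint -> 2
#' @export
resampleSpectrum <- function(wl, values, grid) {
  .check_spectrum(wl, values)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("resampling needs at least 2 non-missing points")
  out <- approx(wl[ok], values[ok], xout = grid, method = "linear",
                rule = 1)$y
  names(out) <- grid
  out
}

#' Standardize a spectrum to zero mean and unit standard deviation
#'
#' Statistics are computed over the full non-missing extent of the spectrum
#' using the sample standard deviation (denominator n - 1); missing
#' positions are preserved. Standardization makes window-fit noise metrics
#' and the oxygen peak height comparable across spectra of very different
#' reflectance magnitude.
#'
#' @inheritParams resampleSpectrum
#' @return Numeric vector of z-values, same length and missingness.
#' @export
standardizeSpectrum <- function(wl, values) {
  .check_spectrum(wl, values)
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("standardization needs at least 2 non-missing values")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) stop("zero-variance spectrum cannot be standardized")
  (values - mean(values[ok])) / s
}

#' Ordinary least-squares polynomial fit over a wavelength window
#'
#' Fits a degree-`degree` polynomial of wavelength to the spectrum values
#' inside the inclusive window `[window[1], window[2]]` and reports the
#' root-mean-square of the residuals with denominator n (the number of
#' fitted points). The wavelength axis is centred before constructing the
#' polynomial basis for numerical stability; `slope` is reported in the
#' original per-nm units.
#'
#' @inheritParams resampleSpectrum
#' @param window length-2 numeric, inclusive wavelength bounds (nm).
#' @param degree polynomial degree (>= 0).
#' @return A list of class `"windowFit"`: `window`, `degree`,
#'   `coefficients` (in the centred basis), `rmse`, `slope` (first-degree
#'   coefficient when `degree == 1`, else `NA`), `n` points fitted.
#' @examples
#' wl <- 750:900
#' f <- fitWindow(wl, 2 + 0.01 * wl, c(750, 900), 1)
#' f$rmse   # 0: a line fits a line exactly
#' @export
fitWindow <- function(wl, values, window, degree) {
  .check_spectrum(wl, values)
  stopifnot(length(window) == 2L, degree >= 0)
  idx <- .window_idx(wl, window[1], window[2])
  x <- wl[idx]
  y <- values[idx]
  ok <- !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(y) < degree + 1L) {
    stop(sprintf("window %g-%g nm has %d usable points; degree %d needs >= %d",
                 window[1], window[2], length(y), degree, degree + 1L))
  }
  xc <- x - mean(x)
  fit <- if (degree == 0L) {
    lm(y ~ 1)
  } else {
    lm(y ~ poly(xc, degree = degree, raw = TRUE))
  }
  res <- structure(
    list(window = as.numeric(window), degree = as.integer(degree),
         coefficients = unname(coef(fit)),
         rmse = sqrt(mean(fit$residuals^2)),
         slope = if (degree == 1L) unname(coef(fit)[2L]) else NA_real_,
         n = length(y)),
    class = "windowFit")
  res
}

#' @export
print.windowFit <- function(x, ...) {
  cat(sprintf("windowFit: degree %d over %g-%g nm (%d points)\n",
              x$degree, x$window[1], x$window[2], x$n))
  cat(sprintf("  rmse: %.6g", x$rmse))
  if (!is.na(x$slope)) cat(sprintf("   slope: %.6g per nm", x$slope))
  cat("\n")
  invisible(x)
}

#' Assemble remote sensing reflectance from water-leaving radiance
#'
#' \eqn{R_{rs}(\lambda) = L_w(\lambda) / E_s(\lambda)}: the ratio of
#' water-leaving radiance just above the surface to above-water downwelling
#' irradiance, both on a common wavelength grid. Wavelengths where either
#' input is missing, or where \eqn{E_s \le 0}, yield `NA` (with a warning
#' reporting the number of non-positive irradiance values).
#'
#' @param lw,es numeric vectors on a common grid (Lw in W m-2 sr-1 nm-1,
#'   Es in W m-2 nm-1), or two \linkS4class{SpectraSet}s with matching
#'   grids and sample IDs.
#' @return Rrs in sr-1, same container type as the inputs.
#' @export
rrsFromLwEs <- function(lw, es) {
  if (is(lw, "SpectraSet") && is(es, "SpectraSet")) {
    return(.rrs_assemble_set(lw, es, function(l, e) rrsFromLwEs(l, e)))
  }
  if (length(lw) != length(es)) stop("Lw and Es must share a grid")
  bad <- !is.na(es) & es <= 0
  if (any(bad)) {
    warning(sprintf("%d wavelengths with non-positive Es set to missing",
                    sum(bad)))
    es[bad] <- NA_real_
  }
  lw / es
}

#' Assemble reflectance from above-water radiance with sky-glint correction
#'
#' \eqn{R_{rs} = (L_t - \rho L_{sky}) / E_s}: the total upwelling radiance
#' seen by an above-water sensor contains sky radiance reflected off the
#' water surface; a constant surface reflectance factor \eqn{\rho} times
#' the simultaneously measured sky radiance is removed before dividing by
#' the downwelling irradiance. The default \eqn{\rho = 0.028} is the
#' conventional flat-sea value; geometry- or wind-dependent models are out
#' of scope.
#'
#' @param lt,lsky,es numeric vectors on a common grid, or three
#'   \linkS4class{SpectraSet}s with matching grids and IDs.
#' @param rho surface reflectance factor for sky radiance, in `[0, 1)`.
#' @return Rrs in sr-1.
#' @export
rrsFromLtLskyEs <- function(lt, lsky, es, rho = 0.028) {
  stopifnot(length(rho) == 1L, rho >= 0, rho < 1)
  if (is(lt, "SpectraSet") && is(lsky, "SpectraSet") && is(es, "SpectraSet")) {
    .check_set_compatible(lt, lsky)
    lw <- SpectraSet(spectraMatrix(lt) - rho * spectraMatrix(lsky),
                     wavelengths(lt), sampleIDs(lt), "Lw")
    return(.rrs_assemble_set(lw, es, function(l, e) rrsFromLwEs(l, e)))
  }
  if (length(lt) != length(lsky) || length(lt) != length(es)) {
    stop("Lt, Lsky and Es must share a grid")
  }
  rrsFromLwEs(lt - rho * lsky, es)
}

.check_set_compatible <- function(a, b) {
  if (!identical(wavelengths(a), wavelengths(b)) ||
      !identical(sampleIDs(a), sampleIDs(b))) {
    stop("SpectraSet inputs must share wavelength grid and sample IDs")
  }
  invisible(NULL)
}

.rrs_assemble_set <- function(num, es, fun) {
  .check_set_compatible(num, es)
  m <- matrix(NA_real_, nrow = nrow(num), ncol = ncol(num))
  nm <- spectraMatrix(num)
  em <- spectraMatrix(es)
  withCallingHandlers(
    for (j in seq_len(ncol(m))) m[, j] <- fun(nm[, j], em[, j]),
    warning = function(w) invokeRestart("muffleWarning"))
  nbad <- sum(!is.na(em) & em <= 0)
  if (nbad > 0) {
    warning(sprintf("%d wavelengths with non-positive Es set to missing", nbad))
  }
  SpectraSet(m, wavelengths(num), sampleIDs(num), "Rrs")
}
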