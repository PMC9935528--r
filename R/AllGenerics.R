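#' @include gloriaqc-package.R
NULL

#' Wavelength grid of a spectral object
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Integer vector of wavelengths in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Radiometric quantity stored in a spectral object
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Single character string, one of `"Rrs"`, `"Es"`, `"Lw"`,
#'   `"Lt"`, `"Lsky"`, `"Lu"`.
#' @export
setGeneric("quantity", function(x) standardGeneric("quantity"))

#' Sample identifiers of a spectral object
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Character vector of sample IDs, in file order.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Spectral value matrix
#'
#' @param x a \linkS4class{SpectraSet}.
#' @return Numeric matrix, wavelengths in rows (named by nm), samples in
#'   columns (named by ID). Missing measurements are `NA`.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Extract one spectrum
#'
#' @param x a \linkS4class{SpectraSet}.
#' @param id sample identifier (single string) or column index.
#' @return Named numeric vector over the wavelength grid.
#' @export
setGeneric("getSpectrum", function(x, id) standardGeneric("getSpectrum"))

#' Run the full quality-control suite
#'
#' @param x a \linkS4class{SpectraSet} holding remote sensing reflectance.
#' @param ... further arguments passed to methods.
#' @return See [runQC,SpectraSet-method].
#' @export
setGeneric("runQC", function(x, ...) standardGeneric("runQC"))
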