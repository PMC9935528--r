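#' @include AllGenerics.R
NULL

.QUANTITIES <- c("Rrs", "Es", "Lw", "Lt", "Lsky", "Lu")

# units used in show() and documentation; Rrs is a ratio, the radiances and
# irradiance are spectral quantities per nm
.QUANTITY_UNITS <- c(
  Rrs  = "sr^-1",
  Es   = "W m^-2 nm^-1",
  Lw   = "W m^-2 sr^-1 nm^-1",
  Lt   = "W m^-2 sr^-1 nm^-1",
  Lsky = "W m^-2 sr^-1 nm^-1",
  Lu   = "W m^-2 sr^-1 nm^-1"
)

#' SpectraSet: a keyed collection of 1 nm spectra of one radiometric quantity
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with one
#' assay `"values"` holding a wavelengths-by-samples matrix of one
#' radiometric quantity on an integer 1 nm wavelength grid (a subset of
#' 350--900 nm). Rows are wavelengths (with `wavelength_nm` in `rowData`),
#' columns are samples keyed by their ID. Missing measurements (wavelengths
#' outside an instrument's range) are `NA`.
#'
#' @slot quantity single string, one of `"Rrs"`, `"Es"`, `"Lw"`, `"Lt"`,
#'   `"Lsky"`, `"Lu"`.
#'
#' @param values numeric matrix, wavelengths in rows and samples in columns.
#' @param wavelengths integer vector of wavelengths (nm), strictly
#'   increasing, one per row of `values`.
#' @param ids character vector of unique sample identifiers, one per column.
#' @param quantity radiometric quantity of the values.
#'
#' @return `SpectraSet()` returns a validated `SpectraSet` object.
#'
#' @examples
#' wl <- 350:900
#' m <- cbind(A = exp(-(wl - 560)^2 / 4000) * 0.01,
#'            B = exp(-(wl - 510)^2 / 6000) * 0.004)
#' ss <- SpectraSet(m, wl, colnames(m), "Rrs")
#' ss
#' range(wavelengths(ss))
#'
#' @aliases SpectraSet
#' @export SpectraSet
#' @exportClass SpectraSet
.SpectraSet <- setClass(
  "SpectraSet",
  contains = "SummarizedExperiment",
  representation(quantity = "character")
)

SpectraSet <- function(values, wavelengths, ids = colnames(values),
                       quantity = c("Rrs", "Es", "Lw", "Lt", "Lsky", "Lu")) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  if (is.null(ids)) {
    ids <- character(0)
  }
  storage.mode(values) <- "double"
  wavelengths <- as.integer(wavelengths)
  rownames(values) <- wavelengths
  colnames(values) <- ids
  se <- SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(wavelength_nm = wavelengths)
  )
  .SpectraSet(se, quantity = quantity)
}

setValidity("SpectraSet", function(object) {
  msg <- character(0)
  if (length(object@quantity) != 1L || !object@quantity %in% .QUANTITIES) {
    msg <- c(msg, sprintf("'quantity' must be one of: %s",
                          paste(.QUANTITIES, collapse = ", ")))
  }
  if (!"values" %in% assayNames(object)) {
    msg <- c(msg, "assay 'values' is required")
  }
  wl <- rowData(object)$wavelength_nm
  if (is.null(wl)) {
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  } else {
    if (anyNA(wl) || any(wl != as.integer(wl))) {
      msg <- c(msg, "wavelengths must be integers (nm)")
    }
    if (length(wl) > 1L && any(diff(wl) <= 0)) {
      msg <- c(msg, "wavelength grid must be strictly increasing")
    }
    if (length(wl) && (min(wl) < 350L || max(wl) > 900L)) {
      msg <- c(msg, "wavelengths must lie within 350..900 nm")
    }
  }
  ids <- colnames(object)
  if (ncol(object) > 0L && (is.null(ids) || anyDuplicated(ids) ||
                            any(is.na(ids)) || any(ids == ""))) {
    msg <- c(msg, "sample IDs must be unique, non-missing and non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet", function(x) {
  as.integer(rowData(x)$wavelength_nm)
})

#' @rdname quantity
#' @export
setMethod("quantity", "SpectraSet", function(x) x@quantity)

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "SpectraSet", function(x) {
  if (is.null(colnames(x))) character(0) else colnames(x)
})

#' @rdname spectraMatrix
#' @export
setMethod("spectraMatrix", "SpectraSet", function(x) assay(x, "values"))

#' @rdname getSpectrum
#' @export
setMethod("getSpectrum", "SpectraSet", function(x, id) {
  if (is.character(id) && !id %in% sampleIDs(x)) {
    stop("unknown sample ID: ", id)
  }
  v <- assay(x, "values")[, id]
  names(v) <- wavelengths(x)
  v
})

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("SpectraSet: %d %s spectra (%s)\n", ncol(object),
              object@quantity, .QUANTITY_UNITS[[object@quantity]]))
  if (length(wl)) {
    cat(sprintf("  wavelengths: %d-%d nm (%d bands, 1 nm grid)\n",
                min(wl), max(wl), length(wl)))
  } else {
    cat("  wavelengths: none\n")
  }
  nmiss <- sum(is.na(assay(object, "values")))
  cat(sprintf("  missing values: %d\n", nmiss))
  invisible(NULL)
})
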