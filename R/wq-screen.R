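#' @include io.R
NULL

#' Water-type-stratified outlier screen for water-quality measurements
#'
#' Within each `Water_type` group (a subjective classification by dominant
#' optical constituent: TSS-dominated, Chla-dominated, CDOM-dominated,
#' Chla+CDOM-dominated, moderately turbid coastal, clear) and for each
#' water-quality variable (`Chla`, `TSS`, `aCDOM_440`, `Secchi_depth`),
#' values are log10-transformed (these attributes are typically
#' log-normally distributed across waters) and entries further than
#' `k` sample standard deviations from the group mean are flagged for
#' re-evaluation. The screen is advisory: it flags, it never removes.
#'
#' Groups with fewer than 2 usable values, or zero dispersion, yield `NA`
#' flags (undeterminable). Non-positive values cannot be log-transformed;
#' they are excluded from the group statistics and reported with
#' `data_error = 1` rather than judged as outliers. With
#' `transform = "none"` the screen runs on raw values (non-positive values
#' are then ordinary data).
#'
#' @param meta data.frame as returned by [readMetadata()]; must contain
#'   `GLORIA_ID`, `Water_type` and at least one water-quality column.
#' @param k threshold in standard deviations (default 3).
#' @param transform `"log10"` (default) or `"none"`.
#' @return data.frame with one row per present (sample, variable) value:
#'   `GLORIA_ID`, `variable`, `water_type`, `value`, `z` (signed distance
#'   from the group mean in screen units), `flag` (tri-state), `group_n`
#'   (usable group size), `data_error`.
#' @export
screenOutliers <- function(meta, k = 3, transform = c("log10", "none")) {
  transform <- match.arg(transform)
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("'k' must be a single positive number")
  }
  if (!all(c("GLORIA_ID", "Water_type") %in% names(meta))) {
    stop("metadata must contain 'GLORIA_ID' and 'Water_type'")
  }
  vars <- intersect(names(.WQ_VARIABLES), names(meta))
  if (length(vars) == 0L) {
    stop("metadata contains none of: ",
         paste(names(.WQ_VARIABLES), collapse = ", "))
  }
  rows <- list()
  for (var in vars) {
    v <- meta[[var]]
    present <- !is.na(v)
    if (!any(present)) next
    d <- data.frame(GLORIA_ID = meta$GLORIA_ID[present],
                    variable = .WQ_VARIABLES[[var]],
                    water_type = as.character(meta$Water_type[present]),
                    value = v[present],
                    stringsAsFactors = FALSE)
    d$data_error <- 0L
    if (transform == "log10") {
      d$data_error[d$value <= 0] <- 1L
      d$screen_value <- ifelse(d$data_error == 1L, NA_real_, log10(d$value))
    } else {
      d$screen_value <- d$value
    }
    d$z <- NA_real_
    d$flag <- NA_integer_
    d$group_n <- 0L
    for (g in unique(d$water_type)) {
      gi <- which(d$water_type %in% g & !is.na(d$screen_value))
      d$group_n[d$water_type %in% g] <- length(gi)
      if (length(gi) < 2L) next
      mu <- mean(d$screen_value[gi])
      sdev <- sd(d$screen_value[gi])
      if (!is.finite(sdev) || sdev == 0) next
      d$z[gi] <- (d$screen_value[gi] - mu) / sdev
      d$flag[gi] <- as.integer(abs(d$z[gi]) > k)
    }
    d$screen_value <- NULL
    rows[[var]] <- d
  }
  out <- do.call(rbind, rows)
  # deterministic order independent of input record order
  out <- out[order(out$variable, out$GLORIA_ID), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a water-quality outlier report
#'
#' @param report data.frame from [screenOutliers()].
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
writeOutlierReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE, quote = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}
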