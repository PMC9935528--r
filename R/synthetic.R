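#' @include wq-screen.R
NULL

.ARTIFACT_TYPES <- c("none", "red_noise", "blue_noise", "baseline_offset",
                     "oxygen_feature", "uv_tilt")

.WATER_TYPES <- c("Clear", "Chla-dominated", "TSS-dominated",
                  "CDOM-dominated", "Chla+CDOM-dominated",
                  "Moderately turbid coastal")

# Per water type: log10 mean and sd of each water-quality variable.
# Chosen to reproduce the broad log-normal spread seen across inland and
# coastal waters (Chla in mg m-3, TSS in g m-3, aCDOM(440) in m-1,
# Secchi depth in m).
.WQ_LOGNORM <- list(
  "Clear"                     = c(chla_mu = -0.3, chla_sd = 0.30, tss_mu = 0.00, tss_sd = 0.30,
                                  cdom_mu = -1.0, cdom_sd = 0.30, sec_mu = 0.90, sec_sd = 0.20),
  "Chla-dominated"            = c(chla_mu = 1.50, chla_sd = 0.40, tss_mu = 1.00, tss_sd = 0.30,
                                  cdom_mu = -0.3, cdom_sd = 0.30, sec_mu = -0.10, sec_sd = 0.20),
  "TSS-dominated"             = c(chla_mu = 0.70, chla_sd = 0.30, tss_mu = 1.90, tss_sd = 0.40,
                                  cdom_mu = -0.3, cdom_sd = 0.30, sec_mu = -0.50, sec_sd = 0.20),
  "CDOM-dominated"            = c(chla_mu = 0.50, chla_sd = 0.30, tss_mu = 0.50, tss_sd = 0.30,
                                  cdom_mu = 0.50, cdom_sd = 0.40, sec_mu = -0.15, sec_sd = 0.20),
  "Chla+CDOM-dominated"       = c(chla_mu = 1.30, chla_sd = 0.35, tss_mu = 0.90, tss_sd = 0.30,
                                  cdom_mu = 0.30, cdom_sd = 0.35, sec_mu = -0.30, sec_sd = 0.20),
  "Moderately turbid coastal" = c(chla_mu = 0.30, chla_sd = 0.30, tss_mu = 0.70, tss_sd = 0.30,
                                  cdom_mu = -0.5, cdom_sd = 0.30, sec_mu = 0.30, sec_sd = 0.20)
)

#' Configuration for the synthetic dataset generator
#'
#' Bundles and validates everything [generateDataset()] needs. Artifact
#' amplitudes default to decisively flagged sizes (see [artifactSpec()]);
#' the generator refuses near-threshold amplitudes so that every expected
#' flag outcome is provable from the construction.
#'
#' @param nSamples number of spectra to generate.
#' @param seed integer seed; all randomness flows from it, so a fixed seed
#'   yields byte-identical output.
#' @param wavelengths integer wavelength extent (default 350:900 at 1 nm).
#' @param artifactWeights named non-negative weights over artifact types
#'   (`none`, `red_noise`, `blue_noise`, `baseline_offset`,
#'   `oxygen_feature`, `uv_tilt`) used to assign one artifact per sample.
#' @param peakWavelength range (nm) for the main reflectance peak, drawn
#'   uniformly; spans the green--red peaks of clear to turbid/eutrophic
#'   waters.
#' @param peakMagnitude range (sr-1) for the peak magnitude, drawn
#'   log-uniformly.
#' @param peakWidth range (nm) of the Gaussian half-width of the main peak.
#' @param outlierFraction fraction of samples per water-quality variable
#'   that receive a planted outlier.
#' @param outlierSigma how far (in true log10 standard deviations) planted
#'   outliers sit from their water-type mean.
#' @param maxAttempts bound on redraws when a candidate base spectrum fails
#'   its cleanliness self-check.
#' @return A list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nSamples = 500L,
                            seed = 20230216L,
                            wavelengths = 350:900,
                            artifactWeights = c(none = 0.5, red_noise = 0.1,
                                                blue_noise = 0.1,
                                                baseline_offset = 0.1,
                                                oxygen_feature = 0.1,
                                                uv_tilt = 0.1),
                            peakWavelength = c(450, 620),
                            peakMagnitude = c(0.002, 0.02),
                            peakWidth = c(50, 85),
                            outlierFraction = 0.01,
                            outlierSigma = 4,
                            maxAttempts = 100L) {
  stopifnot(nSamples >= 0, length(seed) == 1L, is.finite(seed),
            maxAttempts >= 1L,
            outlierFraction >= 0, outlierFraction < 1, outlierSigma > 3,
            peakWavelength[1] >= 450, peakWavelength[2] <= 620,
            peakMagnitude[1] > 0)
  wavelengths <- as.integer(wavelengths)
  if (any(diff(wavelengths) != 1L)) stop("'wavelengths' must be a 1 nm grid")
  missing_w <- setdiff(.ARTIFACT_TYPES, names(artifactWeights))
  if (length(missing_w)) {
    artifactWeights[missing_w] <- 0
  }
  artifactWeights <- artifactWeights[.ARTIFACT_TYPES]
  if (any(artifactWeights < 0) || sum(artifactWeights) <= 0) {
    stop("'artifactWeights' must be non-negative with positive sum")
  }
  structure(list(nSamples = as.integer(nSamples), seed = as.integer(seed),
                 wavelengths = wavelengths,
                 artifactWeights = artifactWeights / sum(artifactWeights),
                 peakWavelength = peakWavelength,
                 peakMagnitude = peakMagnitude, peakWidth = peakWidth,
                 outlierFraction = outlierFraction,
                 outlierSigma = outlierSigma,
                 maxAttempts = as.integer(maxAttempts)),
            class = "syntheticConfig")
}

#' Specify one injectable artifact
#'
#' Artifact amplitudes are expressed in the units the corresponding flag
#' thresholds are defined in, and must be decisively sized: far enough
#' from the threshold (at least 1.5x above, or at most 0.5x, with the
#' derating factors of each construction accounted for) that the expected
#' flag outcome is unambiguous. Near-threshold sizes raise an error.
#'
#' \describe{
#'   \item{`red_noise`, `blue_noise`}{alternating-sign high-frequency
#'     waveform with +/-10\% amplitude jitter, in standardized units,
#'     injected over 790--900 nm (red, clear of the oxygen-band support)
#'     or 350--400 nm (blue). Decisive: amplitude >= 0.36 (red) / 0.23
#'     (blue) for an expected flag, <= 0.10 / 0.075 for expected clean.}
#'   \item{`oxygen_feature`}{Gaussian bump at 762 nm (`width` nm sigma) of
#'     the given standardized amplitude, `sign` +1 (peak) or -1 (dip).
#'     Decisive: >= 0.15 flagged, <= 0.05 clean.}
#'   \item{`uv_tilt`}{linear ramp raising the 350--420 nm end so that the
#'     standardized slope lands near `-amplitude` per nm. Decisive:
#'     amplitude >= 0.009 flagged, <= 0.0025 clean.}
#'   \item{`baseline_offset`}{`sign = +1`: additive offset raising the
#'     minimum/median ratio to `amplitude` (target ratio, decisive >= 0.9);
#'     `sign = -1`: offset pushing a fraction `amplitude` (decisive
#'     >= 0.85) of the 765--900 nm window negative.}
#'   \item{`none`}{no modification; all procedural flags expected 0.}
#' }
#'
#' @param type artifact type.
#' @param amplitude artifact size; defaults to a decisive flag-triggering
#'   size per type.
#' @param sign +1 or -1 (used by `oxygen_feature` and `baseline_offset`).
#' @param width Gaussian sigma (nm) of the oxygen feature.
#' @return A list of class `"artifactSpec"` with the expected outcome of
#'   the targeted flag in `$expected_hit`.
#' @export
artifactSpec <- function(type = .ARTIFACT_TYPES, amplitude = NULL,
                         sign = 1, width = 2) {
  type <- match.arg(type)
  stopifnot(sign %in% c(-1, 1), width > 0, width <= 4)
  if (is.null(amplitude)) {
    amplitude <- switch(type, none = 0, red_noise = 0.45, blue_noise = 0.35,
                        baseline_offset = if (sign > 0) 0.95 else 0.85,
                        oxygen_feature = 0.2, uv_tilt = 0.012)
  }
  hit <- switch(type,
    none = 0L,
    red_noise = if (amplitude >= 0.36) 1L else if (amplitude <= 0.10) 0L else NA,
    blue_noise = if (amplitude >= 0.23) 1L else if (amplitude <= 0.075) 0L else NA,
    oxygen_feature = if (amplitude >= 0.15) 1L else if (amplitude <= 0.05) 0L else NA,
    uv_tilt = if (amplitude >= 0.009) 1L else if (amplitude <= 0.0025) 0L else NA,
    baseline_offset = if (sign > 0) {
      if (amplitude >= 0.9 && amplitude < 1) 1L else NA
    } else {
      if (amplitude >= 0.85 && amplitude < 1) 1L else NA
    })
  if (is.na(hit)) {
    stop("ambiguous artifact size for '", type, "' (", amplitude,
         "): choose a decisive amplitude well clear of the flag threshold")
  }
  structure(list(type = type, amplitude = amplitude, sign = sign,
                 width = width, expected_hit = hit),
            class = "artifactSpec")
}

.gauss <- function(x, mu, s) exp(-((x - mu)^2) / (2 * s^2))

# Cleanliness margins a candidate base spectrum must satisfy, well inside
# every procedural flag threshold, so injected artifacts fully control the
# expected outcome.
.base_is_clean <- function(wl, v) {
  z <- standardizeSpectrum(wl, v)
  ok <- !is.na(v)
  med <- median(v[ok])
  sdr <- sd(v[ok])
  all(
    min(v[ok]) > 0,
    med > 0,
    min(v[ok]) / med <= 0.45,
    fitWindow(wl, z, c(750, 900), 4L)$rmse <= 0.10,
    fitWindow(wl, z, c(350, 400), 4L)$rmse <= 0.075,
    oxygenPeakHeight(wl, v) <= 0.05,
    fitWindow(wl, z, c(350, 420), 1L)$slope >= -0.0025,
    # headroom for alternating blue noise to stay clear of the negative-
    # count branches of the baseline test
    min(v[wl <= 450]) / sdr >= 0.45
  )
}

#' Generate one clean synthetic reflectance spectrum
#'
#' Builds a smooth, strictly positive Rrs shape from a small sum of broad
#' Gaussian components: an ultraviolet shoulder, a main visible peak
#' (450--620 nm), a secondary red component, a sigmoid near-infrared
#' roll-off and a positive floor. Candidate draws are self-checked at
#' generation time: the five procedural flags must be 0 with margin (fit
#' RMSEs at most half their thresholds, oxygen peak height at most 0.05,
#' UV slope at least -0.0025, minimum/median at most 0.45) and the draw is
#' repeated until the check passes or `maxAttempts` is exhausted.
#'
#' Uses the current RNG state; seed control belongs to the caller
#' ([generateDataset()] seeds once from its config).
#'
#' @param config a [syntheticConfig()].
#' @return List with `values` (numeric vector over `config$wavelengths`)
#'   and `params` (the drawn shape parameters).
#' @export
generateBaseSpectrum <- function(config = syntheticConfig()) {
  wl <- config$wavelengths
  for (attempt in seq_len(config$maxAttempts)) {
    p <- runif(1, config$peakWavelength[1], config$peakWavelength[2])
    w <- runif(1, config$peakWidth[1], config$peakWidth[2])
    A <- 10^runif(1, log10(config$peakMagnitude[1]),
                  log10(config$peakMagnitude[2]))
    uv <- runif(1, 0.05, 0.22)
    sec <- runif(1, 0.25, 0.55)
    p2 <- runif(1, 580, 660)
    f <- runif(1, 0.10, 0.16)
    r <- runif(1, 0.08, 0.16)
    l0 <- runif(1, 735, 775)
    s0 <- runif(1, 25, 40)
    shape <- uv * .gauss(wl, 370, 80) + .gauss(wl, p, w) +
      sec * .gauss(wl, p2, 120)
    roll <- r + (1 - r) / (1 + exp((wl - l0) / s0))
    v <- A * (shape * roll + f)
    if (.base_is_clean(wl, v)) {
      return(list(values = v,
                  params = list(peak = p, width = w, magnitude = A,
                                uv = uv, secondary = sec, secondary_peak = p2,
                                floor = f, nir_level = r, rolloff = l0,
                                rolloff_scale = s0, attempts = attempt)))
    }
  }
  stop("failed to draw a clean base spectrum in ", config$maxAttempts,
       " attempts")
}

#' Inject a labelled artifact into a clean spectrum
#'
#' Modifies the spectrum according to an [artifactSpec()] and returns the
#' ground-truth expectation for each procedural flag. Expectations are
#' provable from the construction: artifacts additive in raw units leave
#' standardization-based flags untouched, the alternating-sign noise
#' waveform cannot push more than half of any window negative (so the
#' baseline-shift branches stay off), and injection windows avoid each
#' other's flag supports.
#'
#' @param wl integer wavelength grid of `values`.
#' @param values clean base spectrum (from [generateBaseSpectrum()]).
#' @param artifact an [artifactSpec()] (or a type string, taken with
#'   default decisive amplitude).
#' @return List: `values` (modified spectrum), `expected` (named integer
#'   vector over the five procedural flags), `artifact`.
#' @export
injectArtifact <- function(wl, values, artifact = artifactSpec("none")) {
  if (is.character(artifact)) artifact <- artifactSpec(artifact)
  stopifnot(inherits(artifact, "artifactSpec"))
  .check_spectrum(wl, values)
  ok <- !is.na(values)
  sdr <- sd(values[ok])
  v <- values
  expected <- setNames(rep(0L, length(.PROCEDURAL_FLAGS)), .PROCEDURAL_FLAGS)
  amp <- artifact$amplitude
  hit <- artifact$expected_hit

  if (artifact$type == "red_noise" || artifact$type == "blue_noise") {
    win <- if (artifact$type == "red_noise") c(790L, 900L) else c(350L, 400L)
    idx <- .window_idx(wl, win[1], win[2])
    signs <- (-1)^(seq_along(idx) + sample(0:1, 1))
    v[idx] <- v[idx] + sdr * amp * runif(length(idx), 0.9, 1.1) * signs
    expected[[if (artifact$type == "red_noise") "Noisy_red" else
                "Noisy_blue"]] <- hit
  } else if (artifact$type == "oxygen_feature") {
    v <- v + artifact$sign * sdr * amp * .gauss(wl, 762, artifact$width)
    expected[["Oxygen_signal"]] <- hit
  } else if (artifact$type == "uv_tilt") {
    z <- standardizeSpectrum(wl, values)
    b0 <- fitWindow(wl, z, c(350, 420), 1L)$slope
    m <- b0 + amp
    ramp <- pmax(420 - wl, 0) * m * sdr
    v <- v + ramp
    expected[["Negative_uv_slope"]] <- hit
  } else if (artifact$type == "baseline_offset") {
    med <- median(values[ok])
    if (artifact$sign > 0) {
      delta <- (amp * med - min(values[ok])) / (1 - amp)
      v <- v + delta
    } else {
      nir <- values[.window_idx(wl, 765, 900)]
      delta <- quantile(nir, probs = amp, names = FALSE) + 0.02 * sdr
      v <- v - delta
    }
    expected[["Baseline_shift"]] <- hit
  }
  list(values = v, expected = expected, artifact = artifact)
}

.draw_wq_row <- function(type) {
  par <- .WQ_LOGNORM[[type]]
  tz <- function() max(min(rnorm(1), 2), -2)  # truncated at +/-2 sigma
  c(Chla = 10^(par[["chla_mu"]] + par[["chla_sd"]] * tz()),
    TSS = 10^(par[["tss_mu"]] + par[["tss_sd"]] * tz()),
    aCDOM_440 = 10^(par[["cdom_mu"]] + par[["cdom_sd"]] * tz()),
    Secchi_depth = 10^(par[["sec_mu"]] + par[["sec_sd"]] * tz()))
}

#' Generate a labelled synthetic dataset
#'
#' Draws `nSamples` clean spectra, injects one artifact per sample
#' according to the configured weights, and generates matching metadata
#' with water-type-specific log-normal water-quality values (truncated at
#' +/-2 true standard deviations) plus planted outliers at
#' `outlierSigma` true standard deviations, recorded as ground truth.
#'
#' @param config a [syntheticConfig()].
#' @return List:
#'   \describe{
#'     \item{`spectra`}{\linkS4class{SpectraSet} of Rrs.}
#'     \item{`meta`}{metadata data.frame in the distributed layout.}
#'     \item{`truth`}{list with `flags` (per-sample expected tri-state for
#'       each procedural flag, plus the artifact label) and `wq`
#'       (planted water-quality outliers: `GLORIA_ID`, `variable`,
#'       `direction`).}
#'     \item{`config`}{the configuration used.}
#'   }
#' @export
generateDataset <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  n <- config$nSamples
  wl <- config$wavelengths
  ids <- sprintf("SYN%05d", seq_len(n))

  types <- if (n > 0) {
    sample(.ARTIFACT_TYPES, n, replace = TRUE, prob = config$artifactWeights)
  } else character(0)

  m <- matrix(NA_real_, nrow = length(wl), ncol = n)
  truth_flags <- matrix(NA_integer_, nrow = n, ncol = length(.PROCEDURAL_FLAGS),
                        dimnames = list(NULL, .PROCEDURAL_FLAGS))
  for (i in seq_len(n)) {
    base <- generateBaseSpectrum(config)
    inj <- injectArtifact(wl, base$values, artifactSpec(types[i]))
    m[, i] <- inj$values
    truth_flags[i, ] <- inj$expected
  }

  water_type <- if (n > 0) {
    sample(.WATER_TYPES, n, replace = TRUE)
  } else character(0)
  wq <- t(vapply(water_type, .draw_wq_row, numeric(4)))
  if (n == 0) wq <- matrix(numeric(0), 0, 4,
                           dimnames = list(NULL, c("Chla", "TSS", "aCDOM_440",
                                                   "Secchi_depth")))
  meta <- data.frame(
    GLORIA_ID = ids,
    Water_type = water_type,
    Water_body_type = if (n > 0) {
      sample(c("Lake", "Coastal ocean", "Estuary", "River", "Other"), n,
             replace = TRUE, prob = c(0.60, 0.32, 0.04, 0.02, 0.02))
    } else character(0),
    wq,
    Latitude = round(runif(n, -54, 67), 4),
    Longitude = round(runif(n, -122, 178), 4),
    Measurement_method = sample(1:18, n, replace = TRUE),
    Spectral_resolution_nm = sample(c(1, 3, 10), n, replace = TRUE),
    check.names = FALSE, row.names = NULL
  )

  # plant water-quality outliers at outlierSigma true (log10) standard
  # deviations; at most one per water-type group and variable so the
  # outlier's own inflation of the sample sd stays bounded
  wq_truth <- list()
  n_out <- round(config$outlierFraction * n)
  if (n_out > 0) {
    for (var in names(.WQ_VARIABLES)) {
      cand <- sample(n)
      chosen <- integer(0)
      used_types <- character(0)
      for (i in cand) {
        if (length(chosen) >= n_out) break
        if (water_type[i] %in% used_types) next
        chosen <- c(chosen, i)
        used_types <- c(used_types, water_type[i])
      }
      for (i in chosen) {
        par <- .WQ_LOGNORM[[water_type[i]]]
        key <- switch(var, Chla = "chla", TSS = "tss", aCDOM_440 = "cdom",
                      Secchi_depth = "sec")
        dir <- sample(c(-1, 1), 1)
        meta[[var]][i] <- 10^(par[[paste0(key, "_mu")]] +
                              dir * config$outlierSigma *
                              par[[paste0(key, "_sd")]])
        wq_truth[[length(wq_truth) + 1L]] <-
          data.frame(GLORIA_ID = ids[i], variable = .WQ_VARIABLES[[var]],
                     direction = dir)
      }
    }
  }
  wq_truth <- if (length(wq_truth)) {
    do.call(rbind, wq_truth)
  } else {
    data.frame(GLORIA_ID = character(0), variable = character(0),
               direction = numeric(0))
  }

  list(
    spectra = SpectraSet(m, wl, ids, "Rrs"),
    meta = meta,
    truth = list(
      flags = data.frame(GLORIA_ID = ids, artifact = types, truth_flags,
                         check.names = FALSE, row.names = NULL),
      wq = wq_truth
    ),
    config = config
  )
}
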