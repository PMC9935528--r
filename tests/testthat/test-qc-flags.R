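test_that("red and blue noise flags fire on alternating residuals only", {
  wl <- FULL_GRID
  clean <- peaked_spectrum(wl)
  expect_tri(flagNoisyRed(wl, clean), 0)
  expect_tri(flagNoisyBlue(wl, clean), 0)

  # alternating deviations sized from the frozen oracle RMSEs: 0.3 in
  # standardized units over 750-900 gives rmse ~0.2999 > 0.2, and 0.25
  # over 350-400 gives ~0.2493 > 0.15
  z <- standardizeSpectrum(wl, clean)
  sdr <- sd(clean)
  red <- clean
  idx <- which(wl >= 750)
  red[idx] <- red[idx] + sdr * 0.3 * (-1)^seq_along(idx)
  expect_tri(flagNoisyRed(wl, red), 1)
  expect_tri(flagNoisyBlue(wl, red), 0)

  blue <- clean
  idx <- which(wl <= 400)
  blue[idx] <- blue[idx] + sdr * 0.25 * (-1)^seq_along(idx)
  expect_tri(flagNoisyBlue(wl, blue), 1)
  expect_tri(flagNoisyRed(wl, blue), 0)

  # insufficient wavelength range: undeterminable, not clean
  short <- 400:750
  expect_tri(flagNoisyRed(short, peaked_spectrum(short)), NA)
  expect_tri(flagNoisyBlue(short[short >= 400], peaked_spectrum(short)), NA)
  # zero variance maps to NA, not an error
  expect_tri(flagNoisyRed(wl, rep(1, length(wl))), NA)
})

test_that("baseline shift: up-shifted, down-shifted and clean spectra", {
  wl <- FULL_GRID
  # constant positive spectrum: min equals median, ratio 1 > 0.6
  expect_tri(flagBaselineShift(wl, rep(0.005, length(wl))), 1)
  # typical peaked spectrum: small min/median ratio, no negatives
  expect_tri(flagBaselineShift(wl, peaked_spectrum(wl)), 0)
  # exactly 20 negative values within 350-450 nm trip the UV-blue branch
  v <- peaked_spectrum(wl)
  v[wl %in% 350:369] <- -1e-4
  expect_tri(flagBaselineShift(wl, v), 1)
  # 19 negatives there (and nowhere else) do not reach the 20-count gate
  v <- peaked_spectrum(wl)
  v[wl %in% 350:368] <- -1e-4
  expect_tri(flagBaselineShift(wl, v), 0)
  # >70% negative in 765-900 nm
  v <- peaked_spectrum(wl)
  v[wl >= 790] <- -1e-5
  expect_tri(flagBaselineShift(wl, v), 1)
  # all-NA spectrum is undeterminable
  expect_tri(flagBaselineShift(wl, rep(NA_real_, length(wl))), NA)
})

test_that("the 765-900 nm slope branch works in raw units, not standardized", {
  wl <- FULL_GRID
  # decreasing line crossing zero at 830 nm: 70 of 136 window values are
  # negative (51%, between the 50% and 70% gates) and the raw slope is
  # -2e-6 sr-1 nm-1, below the -8.75e-7 threshold
  v <- peaked_spectrum(wl)
  idx <- wl >= 765
  v[idx] <- 2e-6 * (830 - wl[idx])
  expect_tri(flagBaselineShift(wl, v), 1)
  # scaling by 0.1 lifts the slope above the threshold while leaving every
  # sign (and so every negative-fraction gate) unchanged: flag drops to 0
  expect_tri(flagBaselineShift(wl, 0.1 * v), 0)
})

test_that("oxygen flag thresholds the peak height at 0.1", {
  wl <- FULL_GRID
  expect_tri(flagOxygen(wl, 0.001 + 2e-6 * wl), 0)        # linear: height 0
  expect_tri(flagOxygen(wl, linear_plus_spike(0.25)), 1)  # 0.25 > 0.1
  expect_tri(flagOxygen(wl, linear_plus_spike(0.05)), 0)  # 0.05 < 0.1
  short <- 350:750
  expect_tri(flagOxygen(short, peaked_spectrum(short)), NA)
})

test_that("negative UV slope flag fits the standardized 350-420 nm line", {
  wl <- FULL_GRID
  expect_tri(flagNegativeUvSlope(wl, rep(1, length(wl))), NA)  # zero variance
  flat_then_peak <- peaked_spectrum(wl)
  expect_tri(flagNegativeUvSlope(wl, flat_then_peak), 0)
  # strong decrease from 0.02 to 0.001 across 350-420 then flat: the
  # standardized slope is far below -0.005
  v <- c(seq(0.02, 0.001, length.out = 71), rep(0.001, length(wl) - 71))
  expect_tri(flagNegativeUvSlope(wl, v), 1)
  expect_tri(flagNegativeUvSlope(400:900, peaked_spectrum(400:900)), NA)
})

test_that("QWIP flag is strict at |0.2| and NA without visible coverage", {
  wl <- FULL_GRID
  expect_tri(flagQwip(wl, peaked_spectrum(wl)), 0)
  # a flat spectrum has NDI 0 but AVW ~536 where the polynomial predicts
  # a strongly non-zero NDI: clear failure
  expect_tri(flagQwip(wl, rep(0.004, length(wl))), 1)
  expect_tri(flagQwip(400:600, rep(1, 201)), NA)
  # the threshold is strict: a score at (just under) 0.2 is not flagged,
  # one just over is. Engineer both by shifting the 665 nm band.
  v <- peaked_spectrum(wl)
  shifted <- function(delta) { v2 <- v; v2[wl == 665] <- v2[wl == 665] + delta; v2 }
  score_at <- function(target) {
    uniroot(function(d) qwipScore(wl, shifted(d)) - target,
            c(0, 0.05), tol = 1e-14)$root
  }
  just_under <- shifted(score_at(0.2 - 1e-9))
  expect_lte(abs(qwipScore(wl, just_under)), 0.2)
  expect_tri(flagQwip(wl, just_under), 0)
  just_over <- shifted(score_at(0.2 + 1e-7))
  expect_tri(flagQwip(wl, just_over), 1)
})

test_that("standardization-based flags ignore positive affine rescaling", {
  set.seed(51)
  wl <- FULL_GRID
  specs <- list(
    peaked_spectrum(wl),
    linear_plus_spike(0.25),
    peaked_spectrum(wl, 470, 50) + 0.002 * (-1)^seq_along(wl) *
      (wl >= 750)
  )
  for (v in specs) {
    ref <- c(flagNoisyRed(wl, v), flagNoisyBlue(wl, v),
             flagOxygen(wl, v), flagNegativeUvSlope(wl, v))
    for (a in c(1e-3, 0.5, 40)) {
      got <- c(flagNoisyRed(wl, a * v), flagNoisyBlue(wl, a * v),
               flagOxygen(wl, a * v), flagNegativeUvSlope(wl, a * v))
      expect_identical(got, ref)
    }
  }
})

test_that("flag aggregation treats NA as absence of evidence, not presence", {
  expect_tri(aggregateFlags(0L, 0L, 0L, 0L, 0L, 0L, 0L), 0)
  expect_tri(aggregateFlags(0L, 0L, 0L, 1L, 0L, 0L, NA), 1)
  expect_tri(aggregateFlags(0L, NA, 0L, 0L, 0L, 0L, 0L), 0)
  expect_tri(aggregateFlags(NA, NA, NA), NA)
  expect_tri(aggregateFlags(), NA)
})

test_that("runQC flags every spectrum and carries the Suspect column", {
  wl <- FULL_GRID
  m <- cbind(clean = peaked_spectrum(wl),
             oxygen = linear_plus_spike(0.25),
             upshift = rep(0.005, length(wl)))
  ss <- SpectraSet(m, wl, colnames(m), "Rrs")
  qc <- runQC(ss, suspect = c(clean = 0L, oxygen = 0L, upshift = 1L))
  expect_identical(names(qc), c("flags", "ancillary"))
  f <- qc$flags
  expect_identical(f$GLORIA_ID, colnames(m))
  expect_tri(f$Oxygen_signal[f$GLORIA_ID == "oxygen"], 1)
  expect_tri(f$Flagged[f$GLORIA_ID == "oxygen"], 1)
  expect_tri(f$Baseline_shift[f$GLORIA_ID == "upshift"], 1)
  expect_tri(f$Oxygen_signal[f$GLORIA_ID == "clean"], 0)
  expect_equal(qc$ancillary$Oxygen_peak_height[2], 0.25, tolerance = 1e-10)
  # the constant spectrum cannot be standardized: ancillary NA, flags NA
  expect_tri(f$Noisy_red[f$GLORIA_ID == "upshift"], NA)
  # empty table: empty outputs
  empty <- SpectraSet(matrix(numeric(0), length(wl), 0), wl,
                      character(0), "Rrs")
  qce <- runQC(empty)
  expect_identical(nrow(qce$flags), 0L)
  expect_identical(nrow(qce$ancillary), 0L)
  # wrong quantity refuses to run
  es <- SpectraSet(m, wl, colnames(m), "Es")
  expect_error(runQC(es), "quantity 'Rrs'")
})
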