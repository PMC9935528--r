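test_that("oxygen peak height is the residual from the local linear baseline", {
  wl <- FULL_GRID
  # any spectrum whose standardized form is a straight line has height 0
  expect_equal(oxygenPeakHeight(wl, 0.002 + 1e-5 * wl), 0, tolerance = 1e-12)
  # linear baseline plus an isolated spike: height equals the spike, exactly
  expect_equal(oxygenPeakHeight(wl, linear_plus_spike(0.25, at = 762)), 0.25,
               tolerance = 1e-10)
  # a dip counts through its absolute value
  expect_equal(oxygenPeakHeight(wl, linear_plus_spike(-0.15, at = 761)), 0.15,
               tolerance = 1e-10)
  # spectrum ending before the 745-785 nm support is undeterminable
  short <- 350:750
  expect_true(is.na(oxygenPeakHeight(short, peaked_spectrum(short))))
  expect_true(is.na(oxygenPeakHeight(wl, rep(1, length(wl)))))
})

test_that("oxygen peak height is non-negative and scale-invariant", {
  set.seed(31)
  wl <- FULL_GRID
  for (i in 1:20) {
    v <- peaked_spectrum(wl, peak = runif(1, 450, 620),
                         width = runif(1, 45, 90)) +
      abs(rnorm(1, sd = 5e-4)) * exp(-(wl - 762)^2 / 8)
    h <- oxygenPeakHeight(wl, v)
    expect_gte(h, 0)
    expect_equal(oxygenPeakHeight(wl, v * runif(1, 0.01, 100)), h,
                 tolerance = 1e-10)
  }
})

test_that("AVW is the harmonic mean wavelength weighted by reflectance", {
  wl <- FULL_GRID
  # single-band spectrum: AVW collapses onto that band
  v <- rep(0, length(wl))
  v[wl == 550] <- 0.01
  expect_equal(avw(wl, v), 550)
  # constant spectrum: frozen value from the direct summation oracle
  expect_equal(avw(wl, rep(0.004, length(wl))), 535.98734377841,
               tolerance = 1e-8)
  # coverage and degenerate denominators
  expect_true(is.na(avw(401:900, peaked_spectrum(401:900))))
  expect_true(is.na(avw(wl, -peaked_spectrum(wl))))
})

test_that("AVW lies in the visible range and is scale-invariant", {
  set.seed(41)
  wl <- FULL_GRID
  for (i in 1:25) {
    v <- peaked_spectrum(wl, peak = runif(1, 450, 620),
                         width = runif(1, 45, 90), mag = 10^runif(1, -3, -1))
    a <- avw(wl, v)
    expect_gte(a, 400)
    expect_lte(a, 700)
    expect_equal(avw(wl, v * runif(1, 1e-3, 1e3)), a, tolerance = 1e-10)
  }
})

test_that("NDI contrasts the 665 and 492 nm bands", {
  wl <- FULL_GRID
  base <- rep(0.002, length(wl))
  expect_equal(ndi(wl, base), 0)                       # symmetric bands
  v <- base; v[wl == 492] <- 0
  expect_equal(ndi(wl, v), 1)                          # boundary
  v <- base; v[wl == 492] <- 0.003; v[wl == 665] <- 0.001
  expect_equal(ndi(wl, v), -0.5)
  v <- base; v[wl == 492] <- 0.001; v[wl == 665] <- -0.001
  expect_true(is.na(ndi(wl, v)))                       # zero denominator
  expect_true(is.na(ndi(500:600, rep(1, 101))))        # bands not covered
})

test_that("QWIP score vanishes on-polynomial and is affine in NDI", {
  wl <- FULL_GRID
  p <- qwipCoefficients()
  pv <- function(x) { a <- 0; for (cc in p) a <- a * x + cc; a }
  # two-band construction: solve for the band ratio that puts the NDI
  # exactly on the polynomial at the spectrum's own AVW (independent
  # arithmetic; uniroot on closed-form expressions)
  g <- function(t) {
    a <- (1 + t) / (1 / 492 + t / 665)       # AVW of bands (492: 1, 665: t)
    (t - 1) / (t + 1) - pv(a)
  }
  t0 <- uniroot(g, c(0.05, 20), tol = 1e-14)$root
  v <- rep(0, length(wl))
  v[wl == 492] <- 0.005
  v[wl == 665] <- 0.005 * t0
  expect_equal(qwipScore(wl, v), 0, tolerance = 1e-8)
  # for fixed AVW the score increases strictly with NDI, slope 1
  v2 <- peaked_spectrum(wl)
  s0 <- qwipScore(wl, v2)
  n0 <- ndi(wl, v2)
  a0 <- avw(wl, v2)
  expect_equal(s0, n0 - pv(a0), tolerance = 1e-12)
  # scale invariance
  expect_equal(qwipScore(wl, 37 * v2), s0, tolerance = 1e-10)
})

test_that("chromaticity sits at the white point for flat spectra", {
  wl <- FULL_GRID
  ch <- chromaticity(wl, rep(0.0042, length(wl)))
  expect_equal(ch$x, 1 / 3, tolerance = 1e-6)
  expect_equal(ch$y, 1 / 3, tolerance = 1e-6)
  # scaling leaves chromaticity untouched
  v <- peaked_spectrum(wl)
  ch1 <- chromaticity(wl, v)
  ch2 <- chromaticity(wl, v * 123)
  expect_equal(ch1$x, ch2$x, tolerance = 1e-12)
  expect_equal(ch1$y, ch2$y, tolerance = 1e-12)
  # physical spectra stay inside the triangle
  expect_gt(ch1$x, 0)
  expect_gt(ch1$y, 0)
  expect_lt(ch1$x + ch1$y, 1)
  # a narrow 550 nm spectrum is green: strongly above the white point
  vg <- exp(-(wl - 550)^2 / (2 * 15^2))
  chg <- chromaticity(wl, vg)
  expect_gt(chg$y, 0.5)
  expect_gte(chg$hue_angle, 45)
  expect_lte(chg$hue_angle, 135)
  # insufficient coverage
  expect_true(is.na(chromaticity(500:600, rep(1, 101))$x))
})

test_that("optical water type assignment picks the nearest centroid", {
  wl <- seq(400L, 800L, by = 1L)
  centroids <- sapply(c(480, 560, 640), function(p) {
    exp(-(wl - p)^2 / (2 * 50^2)) + 0.05
  })
  dimnames(centroids) <- list(wl, c("OWT1", "OWT2", "OWT3"))
  expect_identical(assignOWT(wl, centroids[, 2], centroids), "OWT2")
  # spectral angle ignores positive scaling
  expect_identical(assignOWT(wl, 0.37 * centroids[, 3], centroids), "OWT3")
  # exact tie between two centroids resolves to the lowest class
  sym <- cbind(A = c(1, 0, 1), B = c(1, 1, 0))
  rownames(sym) <- c(500L, 550L, 600L)
  probe <- c(1, 0.5, 0.5)
  expect_identical(assignOWT(c(500L, 550L, 600L), probe, sym), "A")
  expect_error(assignOWT(wl, centroids[, 1], centroids[, integer(0)]),
               "at least one centroid")
})
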