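test_that("resampling interpolates linearly and never extrapolates", {
  expect_equal(unname(resampleSpectrum(c(400, 402), c(1, 3), 401)), 2)
  # no extrapolation below the native range
  out <- resampleSpectrum(400:500, rep(1, 101), c(350, 450))
  expect_true(is.na(out[["350"]]))
  expect_equal(out[["450"]], 1)
  # identity on the native grid
  wl <- 400:500
  v <- sin(wl / 20)
  expect_equal(unname(resampleSpectrum(wl, v, wl)), v)
  expect_error(resampleSpectrum(500, 1, 400:500), "at least 2")
})

test_that("standardization gives zero mean, unit sd, and preserves missingness", {
  z <- standardizeSpectrum(1:3 + 400L, c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1))
  wl <- 400:500
  v <- runif(101)
  v[c(5, 50)] <- NA
  z <- standardizeSpectrum(wl, v)
  expect_identical(which(is.na(z)), c(5L, 50L))
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z, na.rm = TRUE), 1)
  # idempotence
  expect_equal(standardizeSpectrum(wl, z), z)
  expect_error(standardizeSpectrum(401:403, c(5, 5, 5)), "zero-variance")
})

test_that("standardization is invariant to positive affine transforms", {
  set.seed(11)
  wl <- FULL_GRID
  v <- peaked_spectrum(wl)
  z <- standardizeSpectrum(wl, v)
  for (a in c(0.01, 3, 1e4)) {
    # offsets in scale with the transformed spectrum; offsets orders of
    # magnitude beyond the signal would only measure float cancellation
    for (b in a * max(v) * c(-0.3, 0, 0.5)) {
      expect_equal(standardizeSpectrum(wl, a * v + b), z, tolerance = 1e-12)
    }
  }
})

test_that("window fits recover exact polynomials and match the LS oracle", {
  wl <- 750:900
  # degree-4 polynomial fitted exactly
  y4 <- 2 + 0.1 * (wl - 800) - 3e-4 * (wl - 800)^2 + 1e-6 * (wl - 800)^4
  f <- fitWindow(wl, y4, c(750, 900), 4)
  expect_equal(f$rmse, 0, tolerance = 1e-8)
  # constant under a line: slope and rmse both 0
  f1 <- fitWindow(wl, rep(2.5, length(wl)), c(750, 900), 1)
  expect_equal(f1$slope, 0)
  expect_equal(f1$rmse, 0)
  # alternating residuals: frozen values from the independent QR oracle
  alt_red <- 0.3 * (-1)^seq_along(wl)
  expect_equal(oracle_polyfit_rmse(wl, alt_red, 4), 0.299901273560278,
               tolerance = 1e-12)
  expect_equal(fitWindow(wl, alt_red, c(750, 900), 4)$rmse,
               0.299901273560278, tolerance = 1e-9)
  wlb <- 350:400
  alt_blue <- 0.25 * (-1)^seq_along(wlb)
  expect_equal(oracle_polyfit_rmse(wlb, alt_blue, 4), 0.249276125597177,
               tolerance = 1e-12)
  expect_equal(fitWindow(wlb, alt_blue, c(350, 400), 4)$rmse,
               0.249276125597177, tolerance = 1e-9)
  # superposition: adding a quartic leaves the residual untouched
  expect_equal(fitWindow(wl, y4 + alt_red, c(750, 900), 4)$rmse,
               0.299901273560278, tolerance = 1e-9)
  expect_error(fitWindow(wl, y4, c(750, 753), 4), "degree 4 needs")
})

test_that("window-fit residuals are orthogonal to the polynomial basis", {
  set.seed(21)
  wl <- 750:900
  y <- peaked_spectrum(wl) + rnorm(length(wl), sd = 1e-4)
  f <- fitWindow(wl, y, c(750, 900), 4)
  xc <- wl - mean(wl)
  fitted <- outer(xc, 0:4, `^`) %*% f$coefficients
  r <- y - as.numeric(fitted)
  for (p in 0:4) {
    expect_lt(abs(sum(r * xc^p)) / sqrt(sum(y^2) * sum(xc^(2 * p))), 1e-8)
  }
})

test_that("reflectance assembly divides radiance by irradiance with guards", {
  expect_equal(rrsFromLwEs(0.005, 1.25), 0.004)
  expect_equal(rrsFromLwEs(0, 1.25), 0)
  expect_warning(out <- rrsFromLwEs(c(0.005, 0.005), c(1.25, 0)),
                 "non-positive Es")
  expect_true(is.na(out[2]))
  expect_true(is.na(rrsFromLwEs(NA_real_, 1.25)))
  # glint-corrected variant
  expect_equal(rrsFromLtLskyEs(0.06, 1.0, 10, rho = 0.028), 0.0032)
  expect_equal(rrsFromLtLskyEs(0.06, 1.0, 10, rho = 0),
               rrsFromLwEs(0.06, 10))
  expect_equal(rrsFromLtLskyEs(0.028, 1.0, 10, rho = 0.028), 0)
  expect_error(rrsFromLtLskyEs(0.06, 1, 10, rho = 1.2), "rho")
})

test_that("glint-corrected reflectance decreases monotonically in rho", {
  wl <- FULL_GRID
  lt <- peaked_spectrum(wl) * 20
  lsky <- 5 + 4 * exp(-(wl - 450)^2 / 2e4)   # sky radiance, strictly positive
  es <- 8 + 2 * exp(-(wl - 500)^2 / 1e5)
  rhos <- c(0, 0.01, 0.028, 0.05, 0.1)
  prev <- rrsFromLtLskyEs(lt, lsky, es, rho = rhos[1])
  for (rho in rhos[-1]) {
    cur <- rrsFromLtLskyEs(lt, lsky, es, rho = rho)
    expect_true(all(cur < prev))
    prev <- cur
  }
})

test_that("assembly on SpectraSet pairs matches the vector computation", {
  wl <- FULL_GRID
  lw <- cbind(A = peaked_spectrum(wl) * 2, B = peaked_spectrum(wl, 500) * 3)
  es <- cbind(A = rep(10, length(wl)), B = 8 + wl / 1000)
  lw_set <- SpectraSet(lw, wl, colnames(lw), "Lw")
  es_set <- SpectraSet(es, wl, colnames(es), "Es")
  rrs <- rrsFromLwEs(lw_set, es_set)
  expect_s4_class(rrs, "SpectraSet")
  expect_identical(quantity(rrs), "Rrs")
  expect_equal(unname(getSpectrum(rrs, "B")),
               unname(rrsFromLwEs(lw[, "B"], es[, "B"])))
  # mismatched IDs refuse to combine
  es_bad <- SpectraSet(es, wl, c("A", "C"), "Es")
  expect_error(rrsFromLwEs(lw_set, es_bad), "share")
})
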