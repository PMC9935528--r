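# Fixtures are built in code; nothing is read from disk.

FULL_GRID <- 350:900

# Smooth, positive, green-peaked reflectance typical of a clear-to-mesotrophic
# water: passes every procedural flag.
peaked_spectrum <- function(wl = FULL_GRID, peak = 550, width = 60,
                            mag = 0.008) {
  mag * (exp(-(wl - peak)^2 / (2 * width^2)) +
           0.4 * exp(-(wl - 630)^2 / (2 * 120^2)) +
           0.15 * exp(-(wl - 380)^2 / (2 * 80^2)) + 0.12) *
    (0.12 + 0.88 / (1 + exp((wl - 760) / 30)))
}

# Independent least-squares oracle: normal equations via QR on the raw
# (centred) Vandermonde matrix -- deliberately not fitWindow().
oracle_polyfit_rmse <- function(x, y, degree) {
  X <- outer(x - mean(x), 0:degree, `^`)
  beta <- qr.solve(X, y)
  r <- y - as.numeric(X %*% beta)
  sqrt(mean(r^2))
}

# Spectrum whose standardized form is exactly a straight line plus an
# isolated deviation of `amp` at `at` nm: the linear coefficient is solved
# so the sample standard deviation is exactly 1, making the standardization
# the identity up to the (irrelevant) mean shift.
linear_plus_spike <- function(amp, at = 762, wl = FULL_GRID) {
  n <- length(wl)
  lc <- wl - mean(wl)
  dpos <- lc[match(at, wl)]
  # sample variance of a*lc + amp*delta is (A a^2 + 2 B a + C0) / (n - 1);
  # solve A a^2 + 2 B a + C = 0 for the positive root so that it equals 1
  A <- sum(lc^2)
  B <- amp * dpos
  C <- amp^2 * (1 - 1 / n) - (n - 1)
  a <- (-B + sqrt(B^2 - A * C)) / A
  v <- a * lc
  v[match(at, wl)] <- v[match(at, wl)] + amp
  v
}

expect_tri <- function(object, expected) {
  expect_identical(object, as.integer(expected))
}
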