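test_that("the PSD grid has step fs/N and N/2+1 one-sided points", {
  set.seed(1)
  sp <- welch_psd(as_demeaned(rnorm(1000), 100))
  expect_length(sp$frequencies, 501)
  expect_equal(diff(sp$frequencies)[1], 0.1)
  expect_equal(sp$frequencies[1], 0)
  expect_equal(sp$frequencies[501], 50)
  expect_true(all(sp$psd >= 0) && all(is.finite(sp$psd)))
  expect_error(welch_psd(as_demeaned(rnorm(8), 100)), "16 samples")
})

test_that("density scaling satisfies Parseval with window power correction", {
  set.seed(10)
  total <- replicate(200, {
    x <- rnorm(1000)
    sp <- welch_psd(as_demeaned(x, 100))
    sum(sp$psd) * 0.1
  })
  expect_equal(mean(total), 1, tolerance = 0.05)
})

test_that("an on-grid sinusoid peaks exactly at its bin", {
  t <- (0:999) / 100
  sp <- welch_psd(as_demeaned(sin(2 * pi * 3 * t), 100))
  expect_equal(sp$frequencies[which.max(sp$psd)], 3.0)
})

test_that("welch_psd equals a directly computed Hamming periodogram", {
  # independent oracle: textbook modified periodogram via explicit DFT sums
  set.seed(12)
  x <- rnorm(64)
  fs <- 50
  n <- 64
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  y <- w * x
  k <- 0:(n / 2)
  dft <- vapply(k, function(kk) {
    abs(sum(y * exp(-2i * pi * kk * (0:(n - 1)) / n)))^2
  }, numeric(1))
  oracle <- dft / (fs * sum(w^2))
  oracle[2:(n / 2)] <- 2 * oracle[2:(n / 2)]
  sp <- welch_psd(as_demeaned(x, fs))
  expect_equal(sp$psd, oracle, tolerance = 1e-12)
})

test_that("the 2-4 Hz band holds 21 inclusive bins on the 0.1 Hz grid", {
  sp <- fake_spectrum(rep(1, 501))
  idx <- which(sp$frequencies >= 2 - 1e-9 & sp$frequencies <= 4 + 1e-9)
  expect_length(idx, 21)
})

test_that("L is exact on flat spectra and linear in log scale", {
  p <- rep(1, 501)
  b <- band_low()
  expect_equal(band_log_amplitude(fake_spectrum(p * 0.37), b), log(0.37))
  # multiplying the PSD by c shifts L by exactly ln c
  set.seed(3)
  p2 <- runif(501, 0.1, 2)
  L1 <- band_log_amplitude(fake_spectrum(p2), b)
  L2 <- band_log_amplitude(fake_spectrum(4 * p2), b)
  expect_equal(L2 - L1, log(4), tolerance = 1e-12)
})

test_that("band integrals match an independent fine-grid quadrature oracle", {
  set.seed(8)
  p <- runif(501, 1e-6, 1)
  sp <- fake_spectrum(p)
  b <- band_low()
  idx <- which(sp$frequencies >= 2 - 1e-9 & sp$frequencies <= 4 + 1e-9)
  f <- sp$frequencies[idx]
  # oracle: trapezoid quadrature of each sampled integrand, evaluated on a
  # 100x refined grid through the integrand's knot values
  ff <- seq(2, 4, by = 0.001)
  lp <- approx(f, log(p[idx]), ff)$y
  fpf <- approx(f, f * p[idx], ff)$y
  pf <- approx(f, p[idx], ff)$y
  fine_trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(band_log_amplitude(sp, b), fine_trapz(ff, lp) / 2, tolerance = 1e-10)
  expect_equal(
    band_mean_frequency(sp, b),
    fine_trapz(ff, fpf) / fine_trapz(ff, pf),
    tolerance = 1e-10
  )
})

test_that("F behaves as a power-weighted centroid", {
  b <- band_low()
  # flat spectrum: midpoint
  expect_equal(band_mean_frequency(fake_spectrum(rep(2, 501)), b), 3.0)
  # single point mass at an interior bin
  p <- rep(0, 501)
  p[33] <- 5 # 3.2 Hz
  expect_equal(band_mean_frequency(fake_spectrum(p), b), 3.2)
  # two point masses: closed-form weighted mean
  p2 <- rep(0, 501)
  p2[26] <- 1 # 2.5 Hz
  p2[36] <- 1 # 3.5 Hz
  expect_equal(band_mean_frequency(fake_spectrum(p2), b), 3.0)
  w1 <- 0.3; w2 <- 1.7
  p3 <- rep(0, 501)
  p3[26] <- w1
  p3[36] <- w2
  expect_equal(
    band_mean_frequency(fake_spectrum(p3), b),
    (2.5 * w1 + 3.5 * w2) / (w1 + w2)
  )
  # scale invariance
  set.seed(9)
  p4 <- runif(501)
  expect_equal(
    band_mean_frequency(fake_spectrum(p4), b),
    band_mean_frequency(fake_spectrum(37.1 * p4), b)
  )
  # zero band power: undefined centroid
  expect_error(band_mean_frequency(fake_spectrum(rep(0, 501)), b), "undefined")
})

test_that("the PSD floor prevents ln 0 and clamping is reported", {
  p <- rep(0, 501)
  p[30] <- 1
  expect_warning(
    L <- band_log_amplitude(fake_spectrum(p), band_low(), floor = 1e-20),
    "clamped"
  )
  expect_true(is.finite(L))
})

test_that("a dominant in-band sinusoid pins F to its frequency within one bin", {
  for (f0 in c(2.1, 3.0, 3.9)) {
    idx <- suppressWarnings(extract_indices(sinusoid_trial(f0, amplitude = 0.2)))
    expect_equal(idx$F[idx$band == "2-4"], f0, tolerance = 0.1)
  }
})

test_that("full-chain extraction is deterministic and respects band contracts", {
  tr <- sinusoid_trial(3, amplitude = 0.1)
  i1 <- suppressWarnings(extract_indices(tr))
  i2 <- suppressWarnings(extract_indices(tr))
  expect_identical(i1, i2)
  expect_equal(i1$band, c("2-4", "10-20"))
  # no 10-20 Hz content: F still inside [10, 20], L far below the low band
  expect_gte(i1$F[2], 10)
  expect_lte(i1$F[2], 20)
  expect_lt(i1$L[2], i1$L[1] - 5)
  # short trial warns
  short <- triaxial_trial("P1", "dominant", "PRE", 100,
    ax = rnorm(800), ay = rnorm(800), az = rnorm(800) + 9.81
  )
  expect_warning(extract_indices(short), "expected")
})

test_that("L of a scaled signal rises by twice the log amplitude factor", {
  tr1 <- sinusoid_trial(3, amplitude = 0.1)
  tr2 <- sinusoid_trial(3, amplitude = 0.2)
  L1 <- suppressWarnings(extract_indices(tr1))$L[1]
  L2 <- suppressWarnings(extract_indices(tr2))$L[1]
  expect_equal(L2 - L1, 2 * log(2), tolerance = 0.02)
})
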