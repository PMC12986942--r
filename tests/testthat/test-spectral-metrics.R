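# Welch PSD, band power, band-limited and residual SNR

test_that("constant signal has ~zero density after constant detrend", {
  psd <- welch_psd(rep(5, 4096), fs = 128, spec = welch_spec(nperseg = 512))
  expect_true(all(psd$density < 1e-20))
})

test_that("white-noise Welch power satisfies Parseval", {
  set.seed(11)
  x <- rnorm(2^17)
  psd <- welch_psd(x, fs = 256, spec = welch_spec())
  df <- psd$freqs[2] - psd$freqs[1]
  expect_equal(sum(psd$density) * df, 1.0, tolerance = 0.05)
  expect_equal(psd$n_segments, 2^17 %/% 1024)
  expect_true(all(psd$density >= 0))
})

test_that("Parseval holds without detrending for stationary signals", {
  set.seed(12)
  fs <- 128
  x <- rnorm(fs * 512) * 2 + sin(2 * pi * 5 * (0:(fs * 512 - 1)) / fs)
  psd <- welch_psd(x, fs = fs,
                   spec = welch_spec(nperseg = 1024, detrend = "none"))
  df <- psd$freqs[2] - psd$freqs[1]
  expect_equal(sum(psd$density) * df, mean(x^2), tolerance = 0.05)
})

test_that("a bin-centered unit sinusoid carries power 1/2", {
  fs <- 128; n <- 2^15
  f0 <- 16 * fs / 1024  # exactly on the Welch grid
  x <- sin(2 * pi * f0 * (0:(n - 1)) / fs)
  psd <- welch_psd(x, fs = fs, spec = welch_spec())
  df <- fs / 1024
  p <- band_power(psd, band_spec(f0 - 2 * df, f0 + 2 * df))
  expect_equal(p, 0.5, tolerance = 0.01)
})

test_that("band_power equals a brute-force inclusive-edge loop", {
  set.seed(13)
  psd <- welch_psd(rnorm(2^13), fs = 64, spec = welch_spec(nperseg = 256))
  df <- psd$freqs[2] - psd$freqs[1]
  for (b in list(band_spec(1, 5), band_spec(0.25, 30), band_spec(10, 31.5))) {
    acc <- 0
    for (k in seq_along(psd$freqs))
      if (psd$freqs[k] >= b$f_lo && psd$freqs[k] <= b$f_hi)
        acc <- acc + psd$density[k] * df
    expect_equal(band_power(psd, b), acc, tolerance = 1e-12)
  }
  # full-grid band equals total power; bin-aligned split is additive
  expect_equal(band_power(psd, band_spec(1e-9, 32)) +
                 psd$density[1] * df,
               band_power(psd), tolerance = 1e-12)
  expect_equal(band_power(psd, band_spec(1, 10 - df / 2)) +
                 band_power(psd, band_spec(10, 20)),
               band_power(psd, band_spec(1, 20)), tolerance = 1e-12)
})

test_that("flat density integrates to about S0 * width", {
  psd <- structure(list(freqs = seq(0, 64, by = 0.25),
                        density = rep(2, 257), fs = 128, n_segments = 1),
                   class = "psd_estimate")
  expect_equal(band_power(psd, band_spec(10, 20)), 2 * 10, tolerance = 2 * 0.25)
})

test_that("band_snr follows its closed form and is scale invariant", {
  # fabricate a PSD holding 90% of its power in [1, 5]
  freqs <- seq(0, 64, by = 0.5)
  density <- rep(0.1 / (length(freqs) - 9) / 0.5, length(freqs))
  inb <- freqs >= 1 & freqs <= 5
  density[inb] <- 0.9 / sum(inb) / 0.5
  psd <- structure(list(freqs = freqs, density = density, fs = 128,
                        n_segments = 1), class = "psd_estimate")
  expect_equal(band_snr(psd, band_spec(1, 5)), 9.542425094393248,
               tolerance = 1e-9)
  # equal split -> 0 dB
  density2 <- density; density2[inb] <- sum(density[!inb]) / sum(inb)
  psd2 <- structure(list(freqs = freqs, density = density2, fs = 128,
                         n_segments = 1), class = "psd_estimate")
  expect_equal(band_snr(psd2, band_spec(1, 5)), 0, tolerance = 1e-9)
  # scaling the signal leaves the ratio unchanged
  psd3 <- psd; psd3$density <- psd$density * 7.3
  expect_equal(band_snr(psd3, band_spec(1, 5)),
               band_snr(psd, band_spec(1, 5)), tolerance = 1e-12)
  # monotone in in-band power at fixed total
  shift <- function(a) {
    d <- density; d[inb] <- d[inb] + a / sum(inb) / 0.5
    d[!inb] <- d[!inb] - a / sum(!inb) / 0.5
    structure(list(freqs = freqs, density = d, fs = 128, n_segments = 1),
              class = "psd_estimate")
  }
  snrs <- sapply(c(0, 0.02, 0.04, 0.06), function(a)
    band_snr(shift(a), band_spec(1, 5)))
  expect_true(all(diff(snrs) > 0))
})

test_that("band_snr sentinels fire on degenerate power splits", {
  freqs <- seq(0, 64, by = 0.5)
  inb <- freqs >= 1 & freqs <= 5
  d_all_in <- ifelse(inb, 1, 0)
  psd_in <- structure(list(freqs = freqs, density = d_all_in, fs = 128,
                           n_segments = 1), class = "psd_estimate")
  expect_warning(v <- band_snr(psd_in, band_spec(1, 5)), "Inf")
  expect_identical(v, Inf)
  psd_out <- structure(list(freqs = freqs, density = 1 - d_all_in, fs = 128,
                            n_segments = 1), class = "psd_estimate")
  expect_warning(v2 <- band_snr(psd_out, band_spec(1, 5)), "Inf")
  expect_identical(v2, -Inf)
})

test_that("residual_snr matches known decompositions", {
  set.seed(14)
  raw <- rnorm(1000)
  expect_equal(residual_snr(raw, raw / 2), 0, tolerance = 1e-12)
  expect_warning(v <- residual_snr(raw, raw), "Inf")
  expect_identical(v, Inf)
  # orthogonal decomposition from disjoint sinusoids with known powers
  fs <- 100; t <- (0:9999) / fs
  s <- 2 * sin(2 * pi * 5 * t)    # power 2
  n <- 0.5 * sin(2 * pi * 20 * t) # power 0.125
  expect_equal(residual_snr(time_series(s + n, fs), time_series(s, fs)),
               10 * log10(2 / 0.125), tolerance = 1e-6)
})

test_that("short records shrink the segment with a warning", {
  expect_warning(psd <- welch_psd(rnorm(500), fs = 128), "shrinking")
  expect_equal(psd$n_segments, 1L)
})

test_that("band-pass filtering raises band SNR on out-of-band noise", {
  set.seed(15)
  fs <- 128; n <- fs * 64
  t <- (0:(n - 1)) / fs
  x <- sin(2 * pi * 2 * t) + rnorm(n)  # in-band tone + broadband noise
  band <- band_spec(0.5, 5)
  raw_snr <- band_snr(welch_psd(x, fs = fs), band)
  filters <- list(
    reza = function(v) reza_filter(time_series(v, fs), band)$samples[, 1],
    butter = function(v)
      apply_zero_phase(imu_butter(), time_series(v, fs))$samples[, 1])
  for (f in filters) {
    filt_snr <- band_snr(welch_psd(f(x), fs = fs), band)
    expect_gt(filt_snr, raw_snr + 3)  # clear margin, not a tie
  }
})

test_that("PSD export writes the two-column dialect", {
  psd <- welch_psd(sin((1:4096) / 5), fs = 64, spec = welch_spec(nperseg = 256))
  path <- withr::local_tempfile(fileext = ".csv")
  write_psd(psd, path)
  back <- read.csv(path)
  expect_named(back, c("frequency_hz", "density"))
  expect_equal(nrow(back), length(psd$freqs))
})
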