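# exponential band-pass core: gain template, edge sharpness, adaptive
# exponent selection, zero-phase frequency-domain application

test_that("distance_to_band is 0 inside and nearest-edge distance outside", {
  b <- band_spec(5, 10)
  expect_equal(distance_to_band(7, b), 0)
  expect_equal(distance_to_band(4, b), 1)
  expect_equal(distance_to_band(12, b), 2)
  expect_equal(distance_to_band(c(5, 10), b), c(0, 0))  # edges are in-band
})

test_that("reza_gain matches the closed form and underflows cleanly", {
  b <- band_spec(5, 10)
  p <- reza_params()  # c = 1, offset = 0.05
  # in-band: offset^d vanishes, gain ~ 1
  expect_equal(reza_gain(7, b, p, d = 10, delta_f = 1), 1, tolerance = 1e-12)
  # one bin outside: frozen value exp(-1.05^10)
  expect_equal(reza_gain(4, b, p, d = 10, delta_f = 1),
               0.1961462691740436, tolerance = 1e-12)
  expect_equal(reza_gain(4, b, p, d = 10, delta_f = 1),
               naive_gain(1, d = 10), tolerance = 1e-14)
  # huge exponent: 1.05^500 overflows exp's range; gain must be exactly 0
  expect_identical(reza_gain(4, b, p, d = 500, delta_f = 1), 0)
})

test_that("gains are bounded, monotone in distance and in d", {
  b <- band_spec(5, 10)
  p <- reza_params()
  freqs <- seq(0, 20, by = 0.01)
  for (d in c(10, 35, 120)) {
    g <- reza_gain(freqs, b, p, d = d, delta_f = 0.01)
    expect_true(all(g >= 0 & g <= 1))
    # non-increasing in band distance
    ord <- order(distance_to_band(freqs, b))
    expect_true(all(diff(g[ord]) <= 1e-12))
  }
  # at fixed out-of-band distance >= 1 bin, gain non-increasing in d
  g_by_d <- sapply(c(10, 15, 20, 50, 200), function(d)
    reza_gain(c(4, 3, 12), b, p, d = d, delta_f = 1))
  expect_true(all(apply(g_by_d, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("edge_sharpness matches scalar re-evaluation at the four bins", {
  # fs = 40, N = 4000: df = 0.01 Hz, both edges land exactly on bins
  fs <- 40; n <- 4000; b <- band_spec(5, 10); p <- reza_params()
  df <- fs / n
  for (d in c(10, 25, 60)) {
    s <- edge_sharpness(d, fs, n, b, p)
    # oracle: in-band gain at the edge bin (u = 0), out-of-band gain one
    # bin outside (u = 1 bin), averaged over the two identical edges
    expect_equal(s, naive_gain(0, d = d) - naive_gain(1, d = d),
                 tolerance = 1e-12)
    expect_true(s >= 0 && s <= 1)
  }
  # ideal limits
  expect_lt(abs(edge_sharpness(5000, fs, n, b, p) - 1), 1e-6)
})

test_that("edge_sharpness errors on a grid too coarse to resolve the band", {
  expect_error(edge_sharpness(10, fs = 40, n_samples = 8,
                              band = band_spec(5, 6), reza_params()),
               "too coarse")
})

test_that("sharpness is non-decreasing in d on scanned grids", {
  for (cfg in list(c(40, 4000), c(128, 8192), c(512, 16384))) {
    b <- if (cfg[1] == 40) band_spec(5, 10) else band_spec(0.5, 5)
    s <- sapply(seq(10, 200, by = 5), edge_sharpness,
                fs = cfg[1], n_samples = cfg[2], band = b,
                params = reza_params())
    expect_true(all(diff(s) >= -1e-12))
    expect_true(all(s <= 1 + 1e-12))
  }
})

test_that("select_exponent matches an exhaustive brute-force scan", {
  brute <- function(fs, n, b, p) {
    ds <- seq(p$d0, p$d_max, by = p$delta_d)
    ss <- sapply(ds, edge_sharpness, fs = fs, n_samples = n, band = b,
                 params = p)
    hit <- which(abs(diff(ss)) < p$tol)[1]
    list(d = ds[hit + 1], sharpness = ss[hit + 1])
  }
  cases <- list(
    list(fs = 40, n = 4000, b = band_spec(5, 10), p = reza_params()),
    list(fs = 128, n = 8192, b = band_spec(0.5, 5), p = reza_params()),
    list(fs = 512, n = 16384, b = band_spec(0.5, 50), p = reza_params()),
    list(fs = 40, n = 4000, b = band_spec(5, 10),
         p = reza_params(offset = 0.5)))
  for (cs in cases) {
    sel <- select_exponent(cs$fs, cs$n, cs$b, cs$p)
    orc <- brute(cs$fs, cs$n, cs$b, cs$p)
    expect_equal(sel$d, orc$d)
    expect_equal(sel$sharpness, orc$sharpness)
    expect_true(sel$converged)
    expect_gte(sel$d, cs$p$d0)
  }
  # fast-saturating template (larger offset) converges no later than the
  # slow one on the same grid
  d_fast <- select_exponent(40, 4000, band_spec(5, 10),
                            reza_params(offset = 0.5))$d
  d_slow <- select_exponent(40, 4000, band_spec(5, 10),
                            reza_params(offset = 0.05))$d
  expect_lte(d_fast, d_slow)
})

test_that("select_exponent caps at d_max with a warning", {
  expect_error(reza_params(tol = 0))  # a zero tolerance is forbidden
  p <- reza_params(tol = 1e-300, d_max = 40)
  expect_warning(sel <- select_exponent(40, 4000, band_spec(5, 10), p),
                 "d_max")
  expect_equal(sel$d, 40)
  expect_false(sel$converged)
})

test_that("reza_filter passes in-band content and removes out-of-band", {
  fs <- 40; n <- 800
  t <- (0:(n - 1)) / fs
  p <- reza_params(pad_mode = "none")
  b <- band_spec(5, 10)
  # zero in, zero out
  z <- reza_filter(time_series(cbind(numeric(n), numeric(n)), fs), b, p)
  expect_true(all(z$samples == 0))
  # band-center sinusoid with integer periods: identity, zero lag
  x7 <- sin(2 * pi * 7 * t)
  y7 <- reza_filter(time_series(x7, fs), b, p)$samples[, 1]
  expect_lt(max(abs(y7 - x7)), 1e-6)
  expect_identical(xcorr_peak_lag(x7, y7), 0L)
  # 7 + 15 Hz mixture: the 15 Hz line must vanish
  x <- x7 + sin(2 * pi * 15 * t)
  y <- reza_filter(time_series(x, fs), b, p)$samples[, 1]
  # oracle: zero the 15 Hz coefficients directly in the input FFT
  X <- fft(x)
  k15 <- 15 / (fs / n)  # exact bin index of the 15 Hz line
  X[c(k15 + 1, n - k15 + 1)] <- 0
  ref <- Re(fft(X, inverse = TRUE)) / n
  expect_lt(sqrt(mean((y - ref)^2)), 1e-3)
  expect_lt(sqrt(mean((y - x7)^2)), 1e-3)
})

test_that("reza_filter is real, linear, and idempotent in-band", {
  fs <- 128; n <- 1024
  p <- reza_params(pad_mode = "none")
  b <- band_spec(0.5, 5)
  set.seed(42)
  x <- rnorm(n); y <- rnorm(n)
  fx <- reza_filter(time_series(x, fs), b, p)$samples[, 1]
  fy <- reza_filter(time_series(y, fs), b, p)$samples[, 1]
  fmix <- reza_filter(time_series(2 * x - 3 * y, fs), b, p)$samples[, 1]
  expect_true(is.numeric(fx))
  expect_equal(fmix, 2 * fx - 3 * fy, tolerance = 1e-12)
  # second application changes band-interior content by < 1e-6 rel. RMS
  ffx <- reza_filter(time_series(fx, fs), b, p)$samples[, 1]
  expect_lt(sqrt(mean((ffx - fx)^2)) / sqrt(mean(fx^2)), 1e-6)
})

test_that("reza_filter matches a naive full-matrix DFT oracle at small N", {
  fs <- 32
  for (n in c(31, 32, 64)) {
    set.seed(n)
    x <- rnorm(n)
    b <- band_spec(4, 8)
    p <- reza_params(pad_mode = "none")
    y <- reza_filter(time_series(x, fs), b, p)$samples[, 1]
    # oracle: explicit DFT matrix, same template, dense linear algebra
    d_sel <- select_exponent(fs, n, b, p)$d
    freqs_full <- (0:(n - 1)) * fs / n
    freqs_folded <- pmin(freqs_full, fs - freqs_full)
    g <- reza_gain(freqs_folded, b, p, d = d_sel, delta_f = fs / n)
    W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
    ref <- Re(Conj(W) %*% (g * (W %*% x))) / n
    expect_equal(y, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("zero-phase property holds for in-band sinusoids (property scan)", {
  fs <- 128; n <- 2048
  b <- band_spec(0.5, 5)
  for (f0 in c(1, 2, 3.5, 4.5)) {
    x <- sinusoid_ts(f0, fs, n)
    y <- reza_filter(x, b)  # default reflect padding
    expect_identical(xcorr_peak_lag(x$samples[, 1], y$samples[, 1]), 0L)
  }
})

test_that("reflect padding preserves length and rate; template is attached", {
  x <- sinusoid_ts(2, 128, 1000)
  y <- reza_filter(x, band_spec(0.5, 5))
  expect_equal(n_samples(y), 1000)
  expect_equal(y$fs, 128)
  tpl <- attr(y, "gain_template")
  expect_s3_class(tpl, "gain_template")
  expect_true(all(tpl$gains >= 0 & tpl$gains <= 1))
  expect_equal(length(tpl$freqs), floor((1000 + 2 * 128) / 2) + 1)
})

test_that("configuration errors are signalled", {
  x <- sinusoid_ts(2, 128, 512)
  expect_error(reza_filter(x, band_spec(0.5, 70)), "Nyquist")
  expect_error(reza_gain(1, band_spec(1, 5), reza_params(), d = -1), "`d`")
  expect_error(reza_params(c = -1))
  expect_error(reza_params(offset = 1.5))
})

test_that("gain template round-trips through its text export", {
  tpl <- reza_template(40, 4000, band_spec(5, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gain_template(tpl, path)
  back <- read.csv(path)
  expect_equal(back$frequency_hz, tpl$freqs, tolerance = 1e-9)
  expect_equal(back$gain, tpl$gains, tolerance = 1e-9)
})
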