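# The Reza exponential band-pass filter: a zero-phase frequency-domain
# magnitude weighting whose gain template is
#
#     G_d(f) = exp(-c * (u(f) + offset)^d)
#
# with u(f) the distance from f to the pass band (0 inside), by default
# normalized to FFT bins. The decay exponent d is not fixed a priori:
# it is grown in steps of delta_d from d0 until the edge sharpness
# S(d) — the average gain jump across one FFT bin at the two band
# edges — stops changing by more than `tol`.

#' Parameters of the exponential band-pass gain template
#'
#' @param c attenuation-rate coefficient, `> 0`. Scales how fast the
#'   gain falls once outside the band.
#' @param offset small positive constant in `(0, 1)` added to the
#'   band distance before exponentiation; keeps the in-band gain at
#'   essentially 1 for any exponent (`offset^d -> 0`).
#' @param d0 initial decay exponent for the adaptive search.
#' @param delta_d fixed step by which the exponent is grown.
#' @param tol convergence tolerance on the change in edge sharpness
#'   between successive exponents.
#' @param d_max hard cap on the exponent search.
#' @param dist_mode `"bins"` (band distance divided by the FFT bin
#'   width, the default) or `"hz"` (raw distance in Hz).
#' @param pad_mode `"reflect"` (default) mirrors `pad_len` samples at
#'   each end before transforming, to soften edge ringing on
#'   finite-length records; `"none"` transforms the bare signal.
#' @param pad_len padding length in samples; `NULL` picks
#'   `min(n - 1, round(fs))`, i.e. about one second per side.
#' @return An object of class `reza_params`.
#' @examples
#' reza_params()                      # package defaults
#' reza_params(offset = 0.5)         # faster-saturating template
#' @export
reza_params <- function(c = 1.0, offset = 0.05, d0 = 10, delta_d = 5,
                        tol = 1e-4, d_max = 1e4,
                        dist_mode = c("bins", "hz"),
                        pad_mode = c("reflect", "none"), pad_len = NULL) {
  dist_mode <- match.arg(dist_mode)
  pad_mode <- match.arg(pad_mode)
  if (c <= 0) stop("`c` must be > 0")
  if (offset <= 0 || offset >= 1) stop("`offset` must lie in (0, 1)")
  if (d0 <= 0 || delta_d <= 0 || tol <= 0) stop("`d0`, `delta_d`, `tol` must be > 0")
  if (d_max <= d0) stop("`d_max` must exceed `d0`")
  structure(list(c = c, offset = offset, d0 = d0, delta_d = delta_d,
                 tol = tol, d_max = d_max, dist_mode = dist_mode,
                 pad_mode = pad_mode, pad_len = pad_len),
            class = "reza_params")
}

#' Distance from a frequency to a pass band
#'
#' Zero for frequencies inside `[f_lo, f_hi]`, otherwise the distance
#' to the nearest band edge. This generalizes the single-cutoff
#' distance `|f - fc|` to a two-edged band with a flat unity interior.
#'
#' @param f frequency (or vector of frequencies) in Hz.
#' @param band a [band_spec()].
#' @return Non-negative distance(s) in Hz.
#' @examples
#' distance_to_band(c(4, 7, 12), band_spec(5, 10))  # 1 0 2
#' @export
distance_to_band <- function(f, band) {
  stopifnot(inherits(band, "band_spec"))
  pmax(band$f_lo - f, f - band$f_hi, 0)
}

#' Exponential band-pass gain template
#'
#' Evaluates `exp(-c * (u + offset)^d)` at each grid frequency, where
#' `u` is the band distance (in FFT bins when `dist_mode = "bins"`,
#' requiring `delta_f`). The power is computed in log space and clamped
#' so that huge exponents underflow cleanly to a gain of exactly 0.
#'
#' @param freqs frequency grid in Hz.
#' @param band a [band_spec()].
#' @param params a [reza_params()].
#' @param d decay exponent, `> 0`.
#' @param delta_f FFT bin width in Hz (required for `dist_mode = "bins"`).
#' @return Gains in `[0, 1]`, one per grid frequency.
#' @export
reza_gain <- function(freqs, band, params = reza_params(), d,
                      delta_f = NULL) {
  stopifnot(inherits(params, "reza_params"))
  if (d <= 0) stop("`d` must be > 0")
  u <- distance_to_band(freqs, band)
  if (params$dist_mode == "bins") {
    if (is.null(delta_f) || delta_f <= 0)
      stop("`delta_f` > 0 is required when dist_mode = \"bins\"")
    u <- u / delta_f
  }
  # (u + offset)^d as exp(d * log(u + offset)), clamped at 700 before
  # the outer negation: beyond exp(700) the gain is indistinguishable
  # from 0 and naive evaluation would overflow for d in the hundreds
  lg <- d * log(u + params$offset)
  pw <- exp(pmin(lg, 700))
  gains <- exp(-pmin(params$c * pw, 700))
  gains[params$c * pw >= 700] <- 0
  gains
}

# one-sided FFT grid for a record of length n at rate fs
fft_grid <- function(fs, n) {
  (0:(floor(n / 2))) * fs / n
}

# indices of the four sharpness evaluation points on the one-sided grid:
# nearest in-band bin to each edge and the adjacent out-of-band bin
edge_bins <- function(freqs, band) {
  inb <- which(freqs >= band$f_lo & freqs <= band$f_hi)
  if (!length(inb))
    stop("frequency grid too coarse: no bin falls inside the band")
  i_lo_in <- min(inb); i_hi_in <- max(inb)
  if (i_lo_in == i_hi_in)
    stop("frequency grid too coarse: cannot separate the four edge evaluation points")
  i_lo_out <- i_lo_in - 1L; i_hi_out <- i_hi_in + 1L
  if (i_lo_out < 1L || i_hi_out > length(freqs))
    stop("frequency grid too coarse: no out-of-band bin adjacent to an edge")
  list(lo_in = i_lo_in, lo_out = i_lo_out, hi_in = i_hi_in, hi_out = i_hi_out)
}

#' Edge sharpness of the gain template
#'
#' The average gain jump across one FFT bin at the two band edges:
#' `S(d) = ((G(fc1) - G(fc1 - df)) + (G(fc2) - G(fc2 + df))) / 2`,
#' with each gain read at the grid point nearest the stated frequency
#' (the nearest in-band bin for the edge terms, the adjacent
#' out-of-band bin for the outside terms). An ideal brick wall scores
#' 1; a flat template scores 0.
#'
#' @param d decay exponent.
#' @param fs sampling rate in Hz.
#' @param n_samples record length defining the FFT grid.
#' @param band a [band_spec()].
#' @param params a [reza_params()].
#' @return Sharpness value in `[0, 1]` for `offset` in `(0, 1)`.
#' @export
edge_sharpness <- function(d, fs, n_samples, band, params = reza_params()) {
  check_band_vs_fs(band, fs)
  freqs <- fft_grid(fs, n_samples)
  delta_f <- fs / n_samples
  idx <- edge_bins(freqs, band)
  g <- reza_gain(freqs[c(idx$lo_in, idx$lo_out, idx$hi_in, idx$hi_out)],
                 band, params, d, delta_f)
  s <- ((g[1] - g[2]) + (g[3] - g[4])) / 2
  if (!is.finite(s)) stop("non-finite sharpness: numerical error")
  s
}

#' Adaptive selection of the decay exponent
#'
#' Grows the exponent from `d0` in steps of `delta_d`, recomputing the
#' edge sharpness each time, and stops at the first exponent whose
#' sharpness differs from the previous one by less than `tol`. The
#' search never exceeds `d_max`; hitting the cap returns `d_max` with
#' `converged = FALSE` and a warning.
#'
#' @inheritParams edge_sharpness
#' @return A list with `d` (the selected exponent), `sharpness` (its
#'   S value), `converged`, and `n_iter`.
#' @examples
#' select_exponent(fs = 40, n_samples = 4000, band = band_spec(5, 10))
#' @export
select_exponent <- function(fs, n_samples, band, params = reza_params()) {
  d <- params$d0
  s_prev <- edge_sharpness(d, fs, n_samples, band, params)
  n_iter <- 1L
  repeat {
    d_next <- d + params$delta_d
    if (d_next > params$d_max) {
      warning(sprintf("exponent search hit d_max = %g without converging",
                      params$d_max))
      return(list(d = params$d_max,
                  sharpness = edge_sharpness(params$d_max, fs, n_samples,
                                             band, params),
                  converged = FALSE, n_iter = n_iter))
    }
    s <- edge_sharpness(d_next, fs, n_samples, band, params)
    n_iter <- n_iter + 1L
    if (abs(s - s_prev) < params$tol)
      return(list(d = d_next, sharpness = s, converged = TRUE,
                  n_iter = n_iter))
    d <- d_next
    s_prev <- s
  }
}

#' Build the gain template for a record configuration
#'
#' Runs [select_exponent()] on the FFT grid of a `(fs, n_samples)`
#' configuration and evaluates the converged template on that grid.
#'
#' @inheritParams edge_sharpness
#' @return An object of class `gain_template`: `freqs`, `gains`,
#'   `d_used`, `sharpness`, `converged`.
#' @export
reza_template <- function(fs, n_samples, band, params = reza_params()) {
  check_band_vs_fs(band, fs)
  sel <- select_exponent(fs, n_samples, band, params)
  freqs <- fft_grid(fs, n_samples)
  gains <- reza_gain(freqs, band, params, sel$d, delta_f = fs / n_samples)
  structure(list(freqs = freqs, gains = gains, d_used = sel$d,
                 sharpness = sel$sharpness, converged = sel$converged),
            class = "gain_template")
}

#' @export
print.gain_template <- function(x, ...) {
  cat(sprintf("<gain_template> %d bins, d = %g, sharpness = %.6f%s\n",
              length(x$freqs), x$d_used, x$sharpness,
              if (x$converged) "" else " (capped)"))
  invisible(x)
}

#' Export a gain template as two-column delimited text
#'
#' @param template a `gain_template` from [reza_template()].
#' @param path output path; columns `frequency_hz`, `gain`.
#' @export
write_gain_template <- function(template, path) {
  stopifnot(inherits(template, "gain_template"))
  utils::write.csv(data.frame(frequency_hz = template$freqs,
                              gain = template$gains),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply the exponential band-pass filter
#'
#' Zero-phase frequency-domain filtering: (optionally) reflect-pad the
#' record, take the FFT, scale every spectral coefficient by the
#' converged gain template (the one-sided template mirrored onto the
#' full grid; the Nyquist bin is weighted like any other grid point),
#' invert, and crop the padding. Real-valued weighting preserves phase
#' exactly, so the filter is offline and noncausal. Multi-channel input
#' is filtered channel by channel on the shared template.
#'
#' @param x a `time_series`.
#' @param band a [band_spec()] strictly inside `(0, fs/2)`.
#' @param params a [reza_params()].
#' @return The filtered `time_series`, same length and sampling rate.
#' @examples
#' t <- (0:799) / 40
#' x <- time_series(sin(2 * pi * 7 * t) + sin(2 * pi * 15 * t), fs = 40)
#' y <- reza_filter(x, band_spec(5, 10), reza_params(pad_mode = "none"))
#' @export
reza_filter <- function(x, band, params = reza_params()) {
  stopifnot(is_time_series(x))
  check_band_vs_fs(band, x$fs)
  if (band$f_lo <= 0) stop("lower band edge must be > 0")
  n <- n_samples(x)
  pad <- 0L
  if (params$pad_mode == "reflect") {
    pad <- if (is.null(params$pad_len)) min(n - 1L, round(x$fs)) else
      min(n - 1L, as.integer(params$pad_len))
  }
  n_fft <- n + 2L * pad
  template <- reza_template(x$fs, n_fft, band, params)
  # mirror the one-sided template onto the full FFT grid
  half <- floor(n_fft / 2)
  idx <- c(0:half, if (n_fft %% 2 == 0) (half - 1):1 else half:1) + 1L
  gains_full <- template$gains[idx]
  out <- apply(x$samples, 2, function(col) {
    xe <- if (pad > 0)
      c(col[(pad + 1):2], col, col[(n - 1):(n - pad)]) else col
    y <- Re(stats::fft(stats::fft(xe) * gains_full, inverse = TRUE)) / n_fft
    if (pad > 0) y[(pad + 1):(pad + n)] else y
  })
  res <- time_series(out, x$fs, labels = x$labels)
  attr(res, "gain_template") <- template
  res
}
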