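#' Uniformly sampled multi-channel time series
#'
#' The universal carrier between all stages of the package: an
#' `n_samples x n_channels` numeric matrix plus its sampling rate in Hz.
#'
#' @param samples numeric vector (one channel) or matrix
#'   (`n_samples x n_channels`); all values must be finite.
#' @param fs sampling rate in Hz, `> 0`.
#' @param labels optional character vector of channel names.
#' @return An object of class `time_series` with elements `samples`
#'   (matrix), `fs` and `labels`.
#' @examples
#' ts <- time_series(sin(2 * pi * 5 * (0:511) / 128), fs = 128)
#' n_samples(ts)
#' @export
time_series <- function(samples, fs, labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (nrow(samples) < 2L)
    stop("a time series needs at least 2 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(samples))
      stop("`labels` length must match the number of channels")
    colnames(samples) <- labels
  }
  structure(list(samples = samples, fs = as.numeric(fs), labels = labels),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples x %d channel(s) @ %g Hz (%.3f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  invisible(x)
}

#' @rdname time_series
#' @param x a `time_series`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname time_series
#' @export
n_channels <- function(x) ncol(x$samples)

#' @rdname time_series
#' @export
is_time_series <- function(x) inherits(x, "time_series")

as_time_series <- function(x, fs = NULL) {
  if (is_time_series(x)) return(x)
  if (is.null(fs)) stop("`fs` is required when `x` is not a time_series")
  time_series(x, fs)
}

# single-channel samples as a plain vector
channel_vector <- function(x, channel = 1L) {
  stopifnot(is_time_series(x))
  as.numeric(x$samples[, channel])
}

#' Frequency band specification
#'
#' A pass band `[f_lo, f_hi]` in Hz. When paired with a sampled signal the
#' band must lie strictly inside `(0, fs/2)`.
#'
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec(0.5, 50)   # canonical EEG analysis band
#' band_spec(0.5, 5)    # gait band
#' @export
band_spec <- function(f_lo, f_hi) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) ||
      length(f_lo) != 1L || length(f_hi) != 1L ||
      !is.finite(f_lo) || !is.finite(f_hi))
    stop("band edges must be single finite numbers")
  if (f_lo <= 0 || f_hi <= f_lo)
    stop("need 0 < f_lo < f_hi")
  structure(list(f_lo = as.numeric(f_lo), f_hi = as.numeric(f_hi)),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> [%g, %g] Hz\n", x$f_lo, x$f_hi))
  invisible(x)
}

check_band_vs_fs <- function(band, fs) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= fs / 2)
    stop(sprintf("band [%g, %g] Hz must lie strictly below Nyquist (%g Hz)",
                 band$f_lo, band$f_hi, fs / 2))
  invisible(TRUE)
}

#' Grand average across channels
#'
#' Collapses a multi-channel recording to one composite trace by taking
#' the arithmetic mean across channels at each sample, the usual
#' whole-head surrogate for high-density EEG. For sensor-array recordings
#' carrying `n_sensors`/`n_axes` attributes (see [generate_imu_like()]),
#' averaging is done in two stages: first across sensors within each
#' axis, then (unless `collapse_axes = FALSE`) across the resulting axis
#' traces.
#'
#' @param x a multi-channel `time_series`.
#' @param collapse_axes for sensor-array input, whether to also average
#'   the per-axis traces down to a single channel (default `TRUE`).
#' @return A `time_series` with one channel (or `n_axes` channels when
#'   `collapse_axes = FALSE` on sensor-array input).
#' @export
grand_average <- function(x, collapse_axes = TRUE) {
  stopifnot(is_time_series(x))
  n_sens <- attr(x, "n_sensors")
  n_axes <- attr(x, "n_axes")
  if (!is.null(n_sens) && !is.null(n_axes) &&
      n_sens * n_axes == n_channels(x)) {
    # channels are sensor-major blocks of axes: sensor1(ax1..axA), sensor2(...)
    axis_mat <- sapply(seq_len(n_axes), function(a) {
      cols <- a + (seq_len(n_sens) - 1L) * n_axes
      rowMeans(x$samples[, cols, drop = FALSE])
    })
    if (!collapse_axes)
      return(time_series(axis_mat, x$fs,
                         labels = paste0("axis", seq_len(n_axes))))
    return(time_series(rowMeans(axis_mat), x$fs, labels = "grand_average"))
  }
  time_series(rowMeans(x$samples), x$fs, labels = "grand_average")
}
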