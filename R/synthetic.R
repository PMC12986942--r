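# Seeded generators for EEG-like and IMU-gait-like multi-channel
# recordings with the spectral structure the benchmark assumes: a
# shared physiological source per subject plus independent per-channel
# sensor noise.

#' Specification of a synthetic EEG-like recording
#'
#' The shared source is a 1/f^alpha background (frequency-domain
#' shaping of white noise) plus narrowband amplitude-modulated
#' oscillations (defaults: alpha rhythm at 10 Hz, beta at 20 Hz), mains
#' line noise, sub-0.5 Hz drift and broadband white noise; each channel
#' adds independent Gaussian sensor noise.
#'
#' @param fs sampling rate in Hz (default 512, typical high-density EEG).
#' @param duration_s record length in seconds (`>= 4`).
#' @param n_channels number of channels (default 8).
#' @param background_slope exponent alpha of the 1/f^alpha background.
#' @param background_sd standard deviation of the background component.
#' @param oscillations list of `c(center_hz, amplitude, bandwidth_hz)`
#'   triples; `amplitude` is the carrier amplitude (power ~ a^2/2).
#' @param line_noise `c(freq_hz, amplitude)` mains component.
#' @param drift `c(cutoff_hz, sd)` slow drift: noise band-limited below
#'   `cutoff_hz` (< 0.5) scaled to standard deviation `sd`.
#' @param white_noise_sd broadband noise added to the shared source.
#' @param channel_noise_sd independent per-channel noise.
#' @return An object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(fs = 512, duration_s = 32, n_channels = 8,
                         background_slope = 1.0, background_sd = 1.0,
                         oscillations = list(c(10, 1.5, 2), c(20, 0.5, 4)),
                         line_noise = c(60, 1.0),
                         drift = c(0.3, 2.0),
                         white_noise_sd = 0.5,
                         channel_noise_sd = 0.5) {
  if (duration_s < 4) stop("`duration_s` must be >= 4")
  if (drift[1] >= 0.5) stop("drift cutoff must be < 0.5 Hz")
  for (o in oscillations)
    if (o[1] >= fs / 2) stop("oscillation center must be below Nyquist")
  amps <- c(background_sd, sapply(oscillations, `[`, 2), line_noise[2],
            drift[2], white_noise_sd, channel_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, n_channels = n_channels,
                 background_slope = background_slope,
                 background_sd = background_sd, oscillations = oscillations,
                 line_noise = line_noise, drift = drift,
                 white_noise_sd = white_noise_sd,
                 channel_noise_sd = channel_noise_sd),
            class = "eeg_sim_spec")
}

#' Specification of a synthetic IMU-gait-like recording
#'
#' The gait component is a stride fundamental plus decaying harmonics
#' (all below ~5 Hz) under slow amplitude modulation; drift, a
#' high-frequency "chatter" band, and white noise are added, and every
#' sensor/axis channel carries independent sensor noise.
#'
#' @param fs sampling rate in Hz (default 128, typical wearable IMU).
#' @param duration_s record length in seconds (must cover >= 10 strides).
#' @param n_sensors,n_axes sensor count and axes per sensor (defaults
#'   6 and 6: tri-axial accelerometer + gyroscope on six bodies).
#' @param stride_hz stride fundamental frequency (default 1 Hz,
#'   comfortable adult walking cadence).
#' @param n_harmonics number of harmonics including the fundamental.
#' @param harmonic_decay multiplicative amplitude decay per harmonic.
#' @param gait_amplitude amplitude of the fundamental.
#' @param chatter `c(low_hz, sd)` high-frequency band noise above
#'   `low_hz` (> 20) with standard deviation `sd`.
#' @param drift `c(cutoff_hz, sd)` slow drift below `cutoff_hz`.
#' @param white_noise_sd broadband noise on the shared source.
#' @param sensor_noise_sd independent per-channel noise.
#' @return An object of class `imu_sim_spec`.
#' @export
imu_sim_spec <- function(fs = 128, duration_s = 64, n_sensors = 6,
                         n_axes = 6, stride_hz = 1.0, n_harmonics = 4,
                         harmonic_decay = 0.6, gait_amplitude = 1.0,
                         chatter = c(25, 0.3),
                         drift = c(0.2, 0.3),
                         white_noise_sd = 0.15,
                         sensor_noise_sd = 0.15) {
  if (duration_s * stride_hz < 10) stop("need at least 10 strides")
  if (stride_hz * n_harmonics >= fs / 2)
    stop("highest harmonic must be below Nyquist")
  if (chatter[2] > 0 && chatter[1] <= 20)
    stop("chatter band must start above 20 Hz")
  amps <- c(gait_amplitude, chatter[2], drift[2], white_noise_sd,
            sensor_noise_sd)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  structure(list(fs = fs, duration_s = duration_s, n_sensors = n_sensors,
                 n_axes = n_axes, stride_hz = stride_hz,
                 n_harmonics = n_harmonics, harmonic_decay = harmonic_decay,
                 gait_amplitude = gait_amplitude, chatter = chatter,
                 drift = drift, white_noise_sd = white_noise_sd,
                 sensor_noise_sd = sensor_noise_sd),
            class = "imu_sim_spec")
}

# white noise spectrally shaped to the given one-sided amplitude
# profile, rescaled to standard deviation sd (0 if sd == 0)
shaped_noise <- function(n, profile, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  half <- floor(n / 2)
  amp_full <- profile[c(0:half, if (n %% 2 == 0) (half - 1):1 else half:1) + 1L]
  y <- Re(stats::fft(W * amp_full, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * sd
}

#' Generate a synthetic EEG-like multi-channel recording
#'
#' Fully deterministic in `(spec, seed)`.
#'
#' @param spec an [eeg_sim_spec()].
#' @param seed integer seed.
#' @return A `time_series` with `spec$n_channels` channels.
#' @export
generate_eeg_like <- function(spec = eeg_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- round(spec$fs * spec$duration_s)
  t <- (0:(n - 1)) / spec$fs
  freqs <- fft_grid(spec$fs, n)
  # 1/f^alpha background: amplitude profile f^(-alpha/2), DC removed
  prof <- c(0, freqs[-1]^(-spec$background_slope / 2))
  src <- shaped_noise(n, prof, spec$background_sd)
  for (o in spec$oscillations) {
    phi <- stats::runif(2, 0, 2 * pi)
    fm <- o[3] / 2
    env <- (1 + 0.5 * sin(2 * pi * fm * t + phi[2])) / sqrt(1 + 0.5^2 / 2)
    src <- src + o[2] * env * sin(2 * pi * o[1] * t + phi[1])
  }
  if (spec$line_noise[2] > 0)
    src <- src + spec$line_noise[2] *
      sin(2 * pi * spec$line_noise[1] * t + stats::runif(1, 0, 2 * pi))
  if (spec$drift[2] > 0) {
    dprof <- as.numeric(freqs > 0 & freqs <= spec$drift[1])
    src <- src + shaped_noise(n, dprof, spec$drift[2])
  }
  if (spec$white_noise_sd > 0)
    src <- src + stats::rnorm(n, sd = spec$white_noise_sd)
  chans <- sapply(seq_len(spec$n_channels), function(ch) {
    src + if (spec$channel_noise_sd > 0)
      stats::rnorm(n, sd = spec$channel_noise_sd) else 0
  })
  time_series(chans, spec$fs,
              labels = paste0("eeg", seq_len(spec$n_channels)))
}

#' Generate a synthetic IMU-gait-like multi-sensor recording
#'
#' Channels are ordered sensor-major (`sensor1_axis1 ... sensor1_axisA,
#' sensor2_axis1, ...`); the sensor/axis layout is attached as
#' attributes so [grand_average()] can average sensors within axes
#' first. Fully deterministic in `(spec, seed)`.
#'
#' @param spec an [imu_sim_spec()].
#' @param seed integer seed.
#' @return A `time_series` with `n_sensors * n_axes` channels.
#' @export
generate_imu_like <- function(spec = imu_sim_spec(), seed = 1L) {
  stopifnot(inherits(spec, "imu_sim_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- round(spec$fs * spec$duration_s)
  t <- (0:(n - 1)) / spec$fs
  freqs <- fft_grid(spec$fs, n)
  # shared gait component: decaying harmonic stack under slow AM
  gait <- numeric(n)
  for (h in seq_len(spec$n_harmonics)) {
    a_h <- spec$gait_amplitude * spec$harmonic_decay^(h - 1)
    gait <- gait + a_h * cos(2 * pi * h * spec$stride_hz * t +
                               stats::runif(1, 0, 2 * pi))
  }
  env <- 1 + 0.2 * sin(2 * pi * 0.05 * t + stats::runif(1, 0, 2 * pi))
  src <- gait * env / sqrt(1 + 0.2^2 / 2)
  if (spec$drift[2] > 0) {
    dprof <- as.numeric(freqs > 0 & freqs <= spec$drift[1])
    src <- src + shaped_noise(n, dprof, spec$drift[2])
  }
  if (spec$chatter[2] > 0) {
    cprof <- as.numeric(freqs >= spec$chatter[1])
    src <- src + shaped_noise(n, cprof, spec$chatter[2])
  }
  if (spec$white_noise_sd > 0)
    src <- src + stats::rnorm(n, sd = spec$white_noise_sd)
  # per-axis gain spreads the shared source across axes; per-channel
  # sensor noise is independent
  axis_gain <- stats::runif(spec$n_axes, 0.7, 1.3)
  n_ch <- spec$n_sensors * spec$n_axes
  chans <- matrix(0, n, n_ch)
  labels <- character(n_ch)
  for (s in seq_len(spec$n_sensors)) {
    for (a in seq_len(spec$n_axes)) {
      j <- (s - 1L) * spec$n_axes + a
      noise <- if (spec$sensor_noise_sd > 0)
        stats::rnorm(n, sd = spec$sensor_noise_sd) else 0
      chans[, j] <- src * axis_gain[a] + noise
      labels[j] <- sprintf("s%d_ax%d", s, a)
    }
  }
  out <- time_series(chans, spec$fs, labels = labels)
  attr(out, "n_sensors") <- spec$n_sensors
  attr(out, "n_axes") <- spec$n_axes
  out
}

# save/restore the global RNG state so generators are pure functions
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
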