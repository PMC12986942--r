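# Welch averaged-periodogram PSD estimation and the band-power / SNR
# outcome measures built on it.

#' Welch estimator settings
#'
#' Defaults follow common practice for physiological recordings: a
#' periodic Hann taper, non-overlapping 1024-sample segments (2 s at
#' 512 Hz, 8 s at 128 Hz), per-segment constant detrending, and density
#' scaling so that summing `density * delta_f` over the one-sided grid
#' recovers the signal variance up to taper bias.
#'
#' @param window taper; only `"hann"` is provided.
#' @param nperseg segment length in samples (`>= 8`).
#' @param noverlap overlap between segments in samples,
#'   `0 <= noverlap < nperseg`.
#' @param detrend `"constant"` (subtract each segment's mean) or
#'   `"none"`.
#' @return An object of class `welch_spec`.
#' @export
welch_spec <- function(window = "hann", nperseg = 1024L, noverlap = 0L,
                       detrend = c("constant", "none")) {
  detrend <- match.arg(detrend)
  window <- match.arg(window, "hann")
  nperseg <- as.integer(nperseg)
  noverlap <- as.integer(noverlap)
  if (nperseg < 8L) stop("`nperseg` must be >= 8")
  if (noverlap < 0L || noverlap >= nperseg)
    stop("need 0 <= noverlap < nperseg")
  structure(list(window = window, nperseg = nperseg, noverlap = noverlap,
                 detrend = detrend, scaling = "density"),
            class = "welch_spec")
}

#' Welch power spectral density estimate
#'
#' Splits the record into (possibly overlapping) segments, detrends and
#' Hann-tapers each, averages the modified periodograms, and returns a
#' one-sided density estimate: `sum(density) * delta_f` approximates
#' the time-domain mean square of the (detrended) signal.
#'
#' @param x a single-channel `time_series`, or a numeric vector with
#'   `fs` supplied.
#' @param spec a [welch_spec()].
#' @param fs sampling rate in Hz when `x` is a plain vector.
#' @return An object of class `psd_estimate`: `freqs` (0 to Nyquist,
#'   spacing `fs/nperseg`), `density` (power per Hz), `fs`,
#'   `n_segments`.
#' @examples
#' set.seed(1)
#' psd <- welch_psd(rnorm(2^14), fs = 128, spec = welch_spec(nperseg = 256))
#' sum(psd$density) * (psd$freqs[2] - psd$freqs[1])  # ~ var(x) = 1
#' @export
welch_psd <- function(x, spec = welch_spec(), fs = NULL) {
  if (is_time_series(x)) {
    if (n_channels(x) != 1L)
      stop("welch_psd expects a single channel; grand_average() first")
    fs <- x$fs
    x <- channel_vector(x)
  }
  if (is.null(fs)) stop("`fs` is required for plain-vector input")
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("non-finite samples in input")
  n <- length(x)
  nper <- spec$nperseg
  nover <- spec$noverlap
  if (n < nper) {
    warning(sprintf("record shorter than nperseg; shrinking segment length to %d", n))
    nper <- n
    nover <- min(nover, nper - 1L)
  }
  step <- nper - nover
  nseg <- (n - nper) %/% step + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nper - 1)) / nper)  # periodic Hann
  starts <- (seq_len(nseg) - 1L) * step
  segs <- vapply(starts, function(s0) x[(s0 + 1):(s0 + nper)],
                 numeric(nper))
  segs <- matrix(segs, nrow = nper)
  if (spec$detrend == "constant")
    segs <- sweep(segs, 2, colMeans(segs))
  segs <- segs * w
  ft <- stats::mvfft(segs)
  half <- nper %/% 2 + 1L
  pxx <- Mod(ft[seq_len(half), , drop = FALSE])^2 / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nper even)
  dbl <- rep(2, half)
  dbl[1] <- 1
  if (nper %% 2 == 0) dbl[half] <- 1
  density <- rowMeans(pxx) * dbl
  structure(list(freqs = (seq_len(half) - 1) * fs / nper,
                 density = as.numeric(density), fs = fs,
                 n_segments = nseg),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins (0-%g Hz, df = %g), %d segment(s)\n",
              length(x$freqs), max(x$freqs), x$freqs[2] - x$freqs[1],
              x$n_segments))
  invisible(x)
}

#' Export a PSD estimate as two-column delimited text
#'
#' @param psd a `psd_estimate`.
#' @param path output path; columns `frequency_hz`, `density`.
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "psd_estimate"))
  utils::write.csv(data.frame(frequency_hz = psd$freqs,
                              density = psd$density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Band-integrated spectral power
#'
#' Rectangle-rule integral of the density over bins with
#' `f_lo <= f_k <= f_hi` (both edges inclusive).
#'
#' @param psd a `psd_estimate`.
#' @param band a [band_spec()], or `NULL` for the full one-sided grid.
#' @return Power in squared signal units.
#' @export
band_power <- function(psd, band = NULL) {
  stopifnot(inherits(psd, "psd_estimate"))
  df <- psd$freqs[2] - psd$freqs[1]
  if (is.null(band)) return(sum(psd$density) * df)
  eps <- df * 1e-9  # guard binary representation of decimal edges
  sel <- psd$freqs >= band$f_lo - eps & psd$freqs <= band$f_hi + eps
  if (!any(sel))
    stop("no PSD bin falls inside the requested band (grid too coarse)")
  sum(psd$density[sel]) * df
}

#' Band-limited signal-to-noise ratio
#'
#' `10 * log10(P_band / (P_total - P_band))` with `P_total` integrated
#' over the full one-sided grid (DC to Nyquist inclusive). Degenerate
#' cases return infinite sentinels with a warning rather than erroring,
#' so batch tables stay rectangular.
#'
#' @param psd a `psd_estimate`.
#' @param band a [band_spec()].
#' @return SNR in dB (possibly `Inf`/`-Inf`).
#' @export
band_snr <- function(psd, band) {
  p_band <- band_power(psd, band)
  p_total <- band_power(psd, NULL)
  p_out <- p_total - p_band
  if (p_out <= 0) {
    warning("no out-of-band power: band SNR is +Inf")
    return(Inf)
  }
  if (p_band <= 0) {
    warning("no in-band power: band SNR is -Inf")
    return(-Inf)
  }
  10 * log10(p_band / p_out)
}

#' Residual signal-to-noise ratio
#'
#' Treats the filtered trace as signal and what the filter removed as
#' noise: `10 * log10(mean(filtered^2) / mean((raw - filtered)^2))`.
#'
#' @param raw,filtered single-channel `time_series` of equal length and
#'   sampling rate (plain vectors also accepted).
#' @return SNR in dB (`Inf` when the residual is identically zero).
#' @export
residual_snr <- function(raw, filtered) {
  r <- if (is_time_series(raw)) channel_vector(raw) else as.numeric(raw)
  f <- if (is_time_series(filtered)) channel_vector(filtered) else as.numeric(filtered)
  if (is_time_series(raw) && is_time_series(filtered) &&
      abs(raw$fs - filtered$fs) > 1e-9)
    stop("sampling rates differ")
  if (length(r) != length(f)) stop("lengths differ")
  p_sig <- mean(f^2)
  p_noise <- mean((r - f)^2)
  if (p_noise == 0) {
    warning("zero residual: SNR is +Inf")
    return(Inf)
  }
  if (p_sig == 0) return(-Inf)
  10 * log10(p_sig / p_noise)
}
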