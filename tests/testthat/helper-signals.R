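# shared fixtures built in code

sinusoid_ts <- function(freq, fs, n, amp = 1, phase = 0) {
  t <- (0:(n - 1)) / fs
  time_series(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

# lag (in samples) of the peak of the input/output cross-correlation;
# 0 means zero-phase
xcorr_peak_lag <- function(x, y, max_lag = 50) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) sum(x[1:(length(x) - L)] * y[(1 + L):length(y)])
    else sum(x[(1 - L):length(x)] * y[1:(length(y) + L)])
  }, numeric(1))
  lags[which.max(cc)]
}

# the three classical EEG-configuration designs plus the IMU variants
eeg_butter <- function() design_iir(iir_design_spec("butterworth", 4,
                                                    band_spec(0.5, 50), 512))
eeg_cheby <- function() design_iir(iir_design_spec("chebyshev1", 4,
                                                   band_spec(0.5, 50), 512,
                                                   rp_db = 0.5))
eeg_ellip <- function() design_iir(iir_design_spec("elliptic", 4,
                                                   band_spec(0.5, 50), 512,
                                                   rp_db = 1, rs_db = 40))
imu_butter <- function() design_iir(iir_design_spec("butterworth", 4,
                                                    band_spec(0.5, 5), 128))

# independent scalar evaluation of the exponential gain (test-side
# oracle; deliberately naive, no log-space guard)
naive_gain <- function(u, c = 1, offset = 0.05, d) exp(-c * (u + offset)^d)
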