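# rezabench

Band-pass filtering shapes every downstream number in EEG and wearable-sensor
gait analysis, yet the classical IIR families force a three-way trade between
passband flatness, ripple, and roll-off steepness. `rezabench` is an R package
for researchers who want to quantify that trade on their own signals. It
implements:

* the **exponential ("Reza") band-pass filter** — a zero-phase frequency-domain
  magnitude weighting with gain template

  ```
  G_d(f) = exp( -c * (u(f) + offset)^d )
  ```

  where `u(f)` is the distance from `f` to the pass band `[fc1, fc2]`
  (0 inside, nearest-edge distance outside, normalized to FFT bins). The decay
  exponent `d` is chosen adaptively: starting from `d0 = 10` it grows in steps
  of `Δd = 5` until the **edge sharpness**

  ```
  S(d) = 1/2 * [ (G_d(fc1) - G_d(fc1 - Δf)) + (G_d(fc2) - G_d(fc2 + Δf)) ]
  ```

  (the mean gain jump across one FFT bin at the two band edges) changes by
  less than `1e-4` between steps. The converged template approaches a
  brick-wall response with a flat unity passband and exactly zero phase.

* the three classical **fourth-order IIR comparators** — Butterworth,
  Chebyshev Type I (Rp = 0.5 dB EEG / 1 dB IMU) and elliptic (Rp = 1 dB,
  Rs = 40 dB) — designed from analog prototypes via prewarped low-pass→band-pass
  and bilinear transforms, realized in second-order sections, applied either
  zero-phase (forward–backward) or causally;

* **outcome measures**: Welch PSD (Hann, no overlap, constant detrend,
  density scaling, `nperseg = 1024`), band-integrated power
  `P_band = Σ S_xx(f_k) Δf` over `f_lo ≤ f_k ≤ f_hi`, band-limited SNR
  `10·log10(P_band / (P_total − P_band))`, and residual SNR
  `10·log10(P_filtered / P_raw−filtered)`;

* **repeated-measures statistics**: one-way within-subject ANOVA with partial
  eta-squared (`η²_p = SS_effect / (SS_effect + SS_error)`) and
  Bonferroni-corrected paired post-hocs (`α_adj = 0.05/6 = 0.0083` for four
  filters);

* seeded **synthetic generators** for EEG-like (1/f background, alpha/beta
  rhythms, line noise, drift; 512 Hz) and IMU-gait-like (1 Hz stride plus
  harmonics, chatter, drift; 128 Hz) multi-channel recordings, with the
  channel/sensor grand-averaging step;

* an end-to-end **benchmark pipeline** and a CLI
  (`inst/cli/rezabench`: `simulate`, `filter`, `metrics`, `response`,
  `benchmark`).

## Worked example

Twenty lines from simulation to statistics:

```r
library(rezabench)

x     <- generate_imu_like(imu_sim_spec(duration_s = 64), seed = 42)
trace <- grand_average(x)              # 36 channels -> 1 composite trace
band  <- band_spec(0.5, 5)             # gait band

y   <- reza_filter(trace, band)
attr(y, "gain_template")
#> <gain_template> 4225 bins, d = 55, sharpness = 1.000000

psd <- welch_psd(y)
band_power(psd, band)                  # 0.727  (signal units^2)
band_snr(psd, band)                    # 42.42 dB (was 6.87 dB unfiltered)

rep <- run_benchmark(benchmark_config("imu", n_subjects = 10, seed = 7))
print(rep)
#> <benchmark_report> imu, 10 subjects, filters: reza, butterworth, chebyshev1, elliptic
#>   band_power    RM-ANOVA: F(3, 27) = 1730, p = 5.854e-31, partial eta^2 = 0.9948 (n = 10, k = 4)
#>   snr_band      RM-ANOVA: F(3, 27) = 47.86, p = 6.124e-11, partial eta^2 = 0.8417 (n = 10, k = 4)
#>   snr_residual  RM-ANOVA: F(3, 27) = 2647, p = 1.924e-33, partial eta^2 = 0.9966 (n = 10, k = 4)

tapply(rep$metrics$band_power$value, rep$metrics$band_power$filter_name, mean)
#> butterworth  chebyshev1    elliptic        reza
#>      0.7912      0.7227      0.6992      0.7960
```

The adaptive search settles at `d = 55` for this 128 Hz / 64 s configuration;
edge sharpness 1.0 means the template jumps from gain 1 to gain 0 within a
single FFT bin. Filtering leaves gait-band power untouched while pushing the
band-limited SNR from 6.9 dB to 42.4 dB. Across ten simulated subjects the
exponential filter retains the most gait-band power, followed by Butterworth,
then Chebyshev, then elliptic — the equiripple designs shave genuine in-band
power — and all six pairwise differences clear the Bonferroni-adjusted
threshold.

## Layout

| module | contents |
| --- | --- |
| `R/reza.R` | gain template, edge sharpness, adaptive exponent, zero-phase FFT filter |
| `R/iir-design.R`, `R/iir-apply.R`, `src/sosfilt.cpp` | analog prototypes, transforms, SOS cascades, filtfilt/causal application |
| `R/welch.R` | Welch PSD, band power, band-limited and residual SNR |
| `R/rm-anova.R` | repeated-measures ANOVA, partial eta-squared, post-hocs |
| `R/synthetic.R` | seeded EEG-like / IMU-gait-like generators |
| `R/benchmark.R`, `R/cli.R` | end-to-end pipeline, report writer, CLI |

See `vignettes/filter-benchmarking.Rmd` for the model assumptions, parameter
rationale, and known limitations.
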