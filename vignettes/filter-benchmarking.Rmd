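---
title: "Exponential band-pass filtering and IIR benchmarking: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exponential band-pass filtering and IIR benchmarking: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rezabench)
```

This vignette is the package's own account of the methods it implements:
the models and their assumptions, the tunable parameters and why their
defaults are what they are, the numerical choices, and what the synthetic
benchmark does and does not establish.

## 1. The exponential band-pass filter

### Model

The filter is defined entirely in the frequency domain. For a record of
length $N$ at sampling rate $f_s$, the one-sided FFT grid is
$f_k = k\,\Delta f$, $\Delta f = f_s/N$. The gain template is

$$G_d(f) = \exp\!\big(-c\,(u(f) + \mathrm{offset})^{d}\big),$$

where $u(f)$ is the distance from $f$ to the pass band $[f_{c1}, f_{c2}]$:
zero inside the band, distance to the nearest edge outside. Filtering
multiplies every FFT coefficient by the (real, non-negative) template and
inverts the transform. Because the weighting is real-valued, the phase of
every retained component is untouched: the filter is exactly zero-phase,
and therefore offline and noncausal.

Two conventions in this definition were genuinely open and are settled as
follows.

* **Band-pass generalization.** The single-cutoff form $|f - f_c|$ is
  extended to a two-edged band via the distance-to-band function. This
  reproduces a flat unity passband (in-band $u = 0$, so
  $G = \exp(-c\,\mathrm{offset}^d) \to 1$ for any growing $d$) and
  symmetric skirts around both edges.
* **Distance units.** The band distance is normalized to FFT bins
  (`dist_mode = "bins"`, i.e. $u/\Delta f$) by default. The edge-sharpness
  functional below measures gain jumps across exactly one bin, and only a
  normalized distance $\ge 1$ makes $(u + \mathrm{offset})^d$ grow with
  $d$ — without this the adaptive loop would have nothing to adapt. A raw
  Hz mode is kept for experimentation.

### Adaptive exponent selection

The steepness exponent $d$ is not fixed a priori. Edge sharpness is the
mean gain jump across one FFT bin at the two edges,

$$S(d) = \tfrac12\Big[\big(G_d(f_{c1}) - G_d(f_{c1} - \Delta f)\big) +
\big(G_d(f_{c2}) - G_d(f_{c2} + \Delta f)\big)\Big],$$

with each gain read at the grid point nearest the stated frequency: the
nearest in-band bin for the edge terms, the adjacent out-of-band bin for
the outside terms (a tie — an edge exactly on a bin — resolves to the
in-band bin for the edge term). Starting from $d_0 = 10$ the search grows
$d$ in fixed steps $\Delta d = 5$ and stops at the first step where
$|S(d) - S(d_\mathrm{prev})| < 10^{-4}$. On a bins-normalized grid $S(d)$
is non-decreasing in $d$ and bounded by 1, so the loop terminates; a hard
cap `d_max` (default $10^4$) guards the pathological limit and returns
with a warning flag rather than an error. The exponent is re-estimated
per $(f_s, N, \text{band})$ configuration — it is a deterministic
function of the recording geometry, not of the data values, so this is
not per-subject tuning.

### Parameter defaults

| parameter | default | why |
| --- | --- | --- |
| `c` | 1.0 | pure scale on the attenuation rate; any positive value yields the same brick-wall limit, 1 keeps the template's one-bin gain interpretable as $e^{-(1+\mathrm{offset})^d}$ |
| `offset` | 0.05 | must be in $(0,1)$ so that in-band gain $\to 1$ and $S(d)$ saturates at 1; the exact value only shapes convergence speed (larger offset converges at smaller $d$) |
| `d0`, `delta_d`, `tol` | 10, 5, $10^{-4}$ | the published loop constants |
| `d_max` | $10^4$ | termination guard, never reached with valid `tol` |
| `pad_mode`, `pad_len` | reflect, $\min(N-1, f_s)$ | about one second of mirrored samples per side softens the FFT's circular-boundary assumption on finite records; `"none"` reproduces the bare algorithm and is what the linearity/oracle tests use |

When padding is active the template is built on the padded length,
because that is the grid actually transformed.

### Numerics

$(u + \mathrm{offset})^d$ is evaluated as $\exp(d \ln(u + \mathrm{offset}))$
with the exponent clamped at 700 before negation; beyond that the gain is
exactly 0 instead of `exp(-Inf)` arithmetic on an overflowed power. This
matters from roughly $d > 300$ at one bin out. Equivalence with a dense
DFT-matrix implementation of the same weighting is asserted to $10^{-10}$
at small $N$, and linearity/realness to machine precision.

## 2. Classical comparators

The three IIR families are designed from their analog low-pass
prototypes — Butterworth poles on the unit circle, Chebyshev-I poles on
an ellipse from $\sinh/\cosh$ of $\mathrm{asinh}(1/\varepsilon)/n$, and
the elliptic prototype from Jacobi elliptic functions evaluated by
descending Landen transformations with the exact degree equation — then
moved to a band-pass via the quadratic $s \to (s^2 + \omega_0^2)/(s\,B)$
root transform and digitized by the bilinear transform with band-edge
prewarping, so the realized response crosses the design edges exactly.
"Fourth-order" means order 4 passed to the design (8 poles in the
band-pass), giving the canonical 24 dB/octave Butterworth skirt.
Sections are paired poles-closest-to-the-unit-circle-first with the
nearest zero pair; any pairing gives the same product transfer function,
this one keeps the cascade well-scaled. During development every
benchmark configuration was cross-checked against an independent
reference implementation to better than $10^{-7}$ dB across the band.

Zero-phase application runs the cascade forward and backward over an
odd-reflection extension of $3(2n_\mathrm{sections} + 1)$ samples per
side with step-matched (unit-step steady-state) initial conditions; the
net magnitude is the squared single-pass magnitude — attenuation in dB
doubles — and the net phase is identically zero. Causal application is a
single pass from rest, as a real-time system would run; it is exposed
behind an explicit flag, but the benchmark defaults to zero-phase for
*all* filters so that phase handling never confounds the outcome
comparison (causal elliptic filtering is a realistic deployment mode,
not a comparable benchmark condition).

`measure_ripple_and_attenuation` quantifies the realized designs.
Passband ripple is the peak-to-peak dB variation between the outermost
in-band local maxima: for equiripple families this equals $R_p$ exactly,
while a maximally flat design reports $\approx 0$ rather than its
$-3$ dB edge roll-off. Stopband attenuation (equiripple-stopband
designs) is the smallest attenuation among stopband ripple maxima, where
the stopband starts at the first crossing of the $R_s$ target moving
away from the band — the stopband edges themselves are not part of the
design specification, so this first-crossing convention is the package's
own.

## 3. Outcome measures

Welch's method averages Hann-tapered, mean-removed, non-overlapping
1024-sample segment periodograms with density scaling (the 1024-sample
default spans 2 s at 512 Hz and 8 s at 128 Hz; it is configurable).
Band power is the rectangle-rule sum $\sum S_{xx}(f_k)\,\Delta f$ over
bins with $f_\mathrm{lo} \le f_k \le f_\mathrm{hi}$, both edges
inclusive. Band-limited SNR is
$10\log_{10}\!\big(P_\mathrm{band}/(P_\mathrm{total} - P_\mathrm{band})\big)$
with $P_\mathrm{total}$ over the full one-sided grid, DC included
(constant detrending makes the DC bin negligible). Degenerate splits
return $\pm\infty$ sentinels with warnings instead of raising, so batch
tables stay rectangular.

Because a well-filtered trace has almost no out-of-band power, its
band-ratio SNR is large and positive; negative values arise only when
out-of-band power dominates, e.g. on raw traces. A residual formulation —
signal = filtered trace, noise = raw − filtered — is provided alongside,
and the benchmark records **both** (`snr_mode = "both"`): on real
recordings the two can rank filters differently, and which of them a
given published number corresponds to is not always recoverable. The
benchmark does not guess; it reports both columns.

## 4. Repeated-measures statistics

The one-way within-subject ANOVA uses the additive two-way decomposition
$SS_\mathrm{total} = SS_\mathrm{subject} + SS_\mathrm{effect} +
SS_\mathrm{error}$ and tests the filter factor on
$(k-1, (k-1)(n-1))$ degrees of freedom, uncorrected for sphericity by
default (a Greenhouse–Geisser option exists behind a flag; published
filter comparisons typically report plain df). Effect size is partial
eta-squared, $SS_\mathrm{effect}/(SS_\mathrm{effect} + SS_\mathrm{error})$,
which satisfies $\eta_p^2 = F\,df_1/(F\,df_1 + df_2)$ — asserted
numerically in the tests. Post-hocs are two-sided paired $t$-tests with
raw $p$ compared against $\alpha_\mathrm{fw}/\binom{k}{2}$
(0.05/6 = 0.0083 for four filters); comparing raw $p$ to an adjusted
$\alpha$ is equivalent to inflating $p$, and matches the adjusted-alpha
framing. Subjects missing any condition are dropped (complete-case),
and a zero-variance error term yields an $F = +\infty$ sentinel with
$p = 0$. The suite includes a seeded null simulation (n = 30, k = 4,
2000 replicates) asserting the empirical type-I rate is $0.05 \pm 0.015$.

## 5. The synthetic stated world

The generators emulate the *spectral structure* the benchmark assumes,
not the biophysics:

* **EEG-like** (512 Hz, 32 s, 8 channels): a shared source of
  $1/f^{1}$ background (frequency-domain shaping of white noise, sd 1),
  amplitude-modulated alpha (10 Hz, amp 1.5) and beta (20 Hz, amp 0.5)
  oscillations, 60 Hz line noise (amp 1), sub-0.5 Hz drift (sd 2) and
  broadband noise (sd 0.5), plus independent per-channel noise (sd 0.5).
* **IMU-gait-like** (128 Hz, 64 s, 6 sensors × 6 axes): a stride
  fundamental at 1 Hz with 4 harmonics decaying by 0.6 per harmonic
  (all ≤ 5 Hz, comfortable-walking territory), slow amplitude
  modulation, drift below 0.2 Hz, a "chatter" band above 25 Hz, white
  noise, per-axis gains and per-channel sensor noise.

Amplitudes were chosen once, before the acceptance suite was run, to
look like plausible grand-averaged physiological traces with clearly
separated in-band and out-of-band structure; they were not adjusted
afterwards. Every generator is a pure function of `(spec, seed)` and
restores the caller's RNG state.

What a green benchmark establishes: on signals whose energy is
concentrated inside the analysis band with separable out-of-band noise,
the exponential filter's flat unity passband retains more band power
than ripple- and roll-off-afflicted comparators, and the within-subject
machinery detects that ordering. What it does **not** establish:
behavior on real recordings with artifacts that straddle the band edges
(muscle activity bleeding into high beta, gait harmonics above 5 Hz),
non-stationarities, or any of the published cohort-level statistics,
which depend on a multi-gigabyte external dataset deliberately outside
this package's scope.

## 6. Known limitations

* No causal/streaming variant of the exponential filter exists — by
  construction it needs the whole record.
* The brick-wall limit implies a long, oscillatory impulse response
  (sinc-like ringing); records with sharp transients near the band
  edges will show edge ringing that the default one-second reflect
  padding only mitigates at the record boundaries, not around interior
  transients. Time-domain diagnostics (impulse/step responses) are the
  appropriate check before trusting steep cutoffs near features of
  interest.
* MAT-container adapters (`eeglab_set`, `matlab_mat`) are declared but
  unsupported in this installation: no MAT reader is available in the
  dependency budget, so those formats raise an informative error and
  the delimited dialect is the interchange path.
* The elliptic stopband-edge convention (first crossing of the $R_s$
  target) and the outermost-maxima ripple convention are measurement
  choices of this package; alternative conventions would report the
  same equiripple designs identically but could differ on exotic
  responses.
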