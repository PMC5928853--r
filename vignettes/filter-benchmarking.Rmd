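---
title: "Benchmarking filters for short PPG records with the skewness SQI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking filters for short PPG records with the skewness SQI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgsqi)
```

## The quality model

A clean photoplethysmogram beat is asymmetric: a steep systolic upstroke
and peak, then a slow diastolic decay carrying the tidal and dicrotic
waves. That asymmetry makes the amplitude distribution of a clean window
right-skewed, while additive wander, powerline pickup and broadband noise
pull it back toward symmetry. The skewness statistic

$$S_{SQI} = \frac{1}{N}\sum_{i=1}^{N}\left(\frac{x_i-\hat\mu_x}{\sigma}\right)^3$$

is therefore a cheap, single-pass signal quality index: larger is cleaner.
`ppg_skewness()` implements the moment form above with the population
($1/N$) standard deviation, matching the third-standardized-moment
definition; a $1/(N-1)$ variant is available via `sd_estimator = "sample"`
but is off by default. The statistic is invariant under positive affine
rescaling — so amplifier gain and DC offset do not matter — and flips sign
if the waveform is inverted.

**Windowing.** `windowed_sqi()` scores consecutive, non-overlapping 1-s
windows, left-aligned at the first sample, and takes the record-level SQI
as the *maximum* window value; a trailing remainder shorter than one window
is dropped (a 2.1-s record at 1 kHz yields exactly two windows). Overlap
and remainder handling are genuinely open choices; non-overlapping
left-aligned windows are the simplest deterministic reading and make the
window count `floor(duration / window)`. The max rule rewards a record that
contains at least one clean second.

**Degenerate windows.** A constant window has no defined skewness. We
return 0 with a warning rather than an error, so a benchmark sweep over 90
configurations never aborts because some aggressive filter flattened one
window of one record. Zero is the natural choice: it is the skewness limit
of a symmetric degenerate distribution, and it marks the window as
pulse-free, which is the correct quality verdict.

## The filter bank

Nine families, ten orders each (`enumerate_bank()`, 90 configurations).
"Order" means the family's natural size parameter:

| family | order grid | meaning |
|---|---|---|
| moving_average, median | 0.05–0.50 s | centered window length |
| fir_hamming, fir_ls | 0.05–0.50 s | tap span; `round(len * fs)` + 1 taps |
| butterworth, cheby1, cheby2, elliptic | 2–20 (even) | bandpass design order |
| wavelet | 1–10 | MODWT decomposition level |

Window lengths are specified in seconds, not samples, so the grid is
portable across sampling rates; they convert by `round(len * fs)` and the
sliding windows are forced odd for a symmetric, phase-free operation.

For the IIR families the order is the *design-function argument*: a
bandpass of design order $N$ has $2N$ poles (effective order $2N$), so the
recommended "4th-order" Chebyshev II is an 8-pole filter realized as 4
biquads. This matches the convention of the design functions in the major
numerical environments, and we document it prominently because "order" is
the single most ambiguous word in filter comparisons.

Fixed design constants: 0.1 dB passband ripple (Chebyshev I, elliptic),
20 dB stopband attenuation (Chebyshev II), 30 dB (elliptic). All are
overridable per `filter_spec()` and in the YAML config.

**Passband.** No single passband suits every study; we default to
0.5–8 Hz, which covers resting heart rates (0.7–2 Hz fundamentals) plus
the first few harmonics that shape the dicrotic notch, while excluding
typical wander (< 0.5 Hz) and powerline/EMG energy. The band is a
parameter everywhere and every report records the band used.

**Numerical realization.** High-order bandpass transfer functions are
numerically unusable in polynomial form, so all IIR designs are carried
through zero–pole–gain form end to end: analog lowpass prototype
(Butterworth/Chebyshev closed forms; Cauer prototype for the elliptic
family), lowpass→bandpass spectral transform with bilinear prewarping so
the band edges land exactly, then pole/zero pairing into second-order
sections — conjugate pairs together, real roots paired outermost-with-
innermost, each pole pair matched to the nearest remaining zero pair,
overall gain spread evenly across sections, least-damped sections last.
A design whose realized sections are not strictly stable raises an error
rather than returning silently; a test sweeps the entire 40-design IIR
grid for stability.

The least-squares FIR design solves the classic closed-form normal
equations for an even-order linear-phase filter against a piecewise-
constant desired response (stopbands at `f_low - 0.2` Hz and
`f_high + 2` Hz; the lower stopband edge is clamped to `f_low / 2` with a
warning if the subtraction would make it non-positive). The wavelet
denoiser is a maximal-overlap (shift-invariant) discrete wavelet transform
with the db2 wavelet, implemented in the frequency domain on a
reflection-extended series, with level-dependent noise estimates
(median absolute deviation / 0.6745) and the universal soft threshold
$\hat\sigma_j\sqrt{2\log N}$.

## Zero-phase application

Linear filters are applied forward and backward (`apply_zero_phase()`):
the effective magnitude response is the squared single-pass response and
the phase is identically zero, so systolic feet, peaks and notches stay
where they were. Before filtering, the record is extended by odd
reflection — `min(3 * effective_order, n - 1)` samples per side — and each
causal pass starts from the steady-state step initial conditions, so the
start-up transient scales with the signal's deviation from its edge value
rather than with its absolute level.

Two numerical facts matter for 2.1-s records and deserve honesty:

* The bandpass poles sit within $10^{-3}$ of the unit circle, so their
  impulse responses outlast both the padding and often the record itself.
  Forward–backward application is therefore *exactly* zero-phase but not
  *exactly* reversal-symmetric: filtering the time-reversed record and
  reversing agrees with the direct output to machine precision for FIR
  designs, but only to edge-transient level (order $10^{-3}$ relative on a
  tapered in-band tone) for the IIR designs. The zero-delay property
  itself is sharp: a filtered narrowband pulse cross-correlates with its
  input with the peak at lag 0, which the tests assert for every family.
* Stopband measurements on short records are transient-limited. An
  untapered out-of-band tone has boundary kinks whose in-band spectral
  content leaks through the passband and dominates the output; tests
  therefore probe the stopband with tapered tones and verify the design's
  own frequency response separately.

The moving-average and median filters are applied as centered sliding
windows whose span truncates at the record boundaries (so a constant
record passes through unchanged); the interior of the median filter runs
through `stats::runmed`, the boundary columns through explicit truncated
medians. The wavelet denoiser is zero-phase by construction.

## The benchmark

`run_benchmark()` filters every labeled record with every configuration
and averages record SQIs per quality grade; `normalize_scores()` min–max
normalizes each grade across the 90 configurations (raw baselines are
reported separately and are not part of the normalization domain);
`rank_configurations()` orders configurations by the *sum* of the three
normalized scores — the height of a stacked per-grade bar. The sum is the
natural scalarization of a stacked histogram; no grade is privileged.
Ties break toward the lower order (cheaper to run, less ringing), then
family name. `report_benchmark()` writes the full 270-row grid as CSV plus
a plain-text summary, and identical runs produce bit-identical files.

## The synthetic generator

`synth_ppg_record()` emulates the study's records: 2.1 s at 1 kHz,
12-bit amplitude (rounded, clipped to 0–4095). Each beat is a
two-Gaussian template — systolic wave (amplitude 1, center 0.30 of the
period, width 0.10) and diastolic wave (amplitude 0.4, center 0.62, width
0.14) — standard synthetic-PPG practice; the parameters are exposed, not
claimed physiological. Heart rate defaults to one draw per record from
N(73, 10) beats/min truncated to 40–120, matching the cohort's resting
distribution, with 3% per-beat multiplicative period jitter so the
waveform is never exactly periodic. Noise presets per grade add baseline
wander (sinusoid below 0.5 Hz), white noise, 50 Hz powerline pickup, and
(for the poorer grades) a motion-artifact burst: G1 is nearly clean, G2
has wander and noise that obscure the diastolic wave, G3 is
noise-dominated (combined noise amplitude exceeding the beat train). The
presets are calibrated fixtures chosen once so that the three grades
separate in raw SQI; they are test conditions, not physiology.

What passing tests on this generator do show: the SQI statistic orders the
grades correctly; the recommended filter raises the SQI of
moderate-quality records; sharp-transition bandpass families outrank
smoothing families when the noise is out-of-band. What they cannot show:
behavior on real probe data, whose artifacts (saturation, probe-coupling
changes, pulse-shape pathology) the generator does not model, and any
universal claim that one specific order wins — on finite cohorts the
top-ranked Chebyshev II order varies with the noise realization, while the
family-level conclusion is stable.

## Problem sizes and determinism

The test suite exercises the full 90-configuration benchmark on a
30-records-per-grade cohort, and `scripts/acceptance.R` runs the study's
own group sizes (36/132/51); both complete in minutes on one CPU. All
randomness flows from explicit integer seeds: records are deterministic
functions of `(grade, geometry, seed, models)`, dataset-level seeds derive
per-record seeds below $2^{31}$, and generation never disturbs the
session RNG. Benchmarks contain no randomness at all, which is what makes
bit-identical reports possible.

## Known limitations

* The elliptic analog prototype is computed by Cauer-filter routines whose
  stopband floor can deviate from nominal by up to ~1 dB at design orders
  above 14; the Chebyshev and Butterworth prototypes are closed-form exact.
* Reversal symmetry of IIR zero-phase filtering is edge-transient-limited
  (see above); applications needing exact symmetry should use the FIR
  designs.
* The benchmark's ranking criterion (sum of per-grade normalized means)
  is one defensible scalarization; alternatives (weighting grades by
  prevalence, rank aggregation) are easy to add on top of the returned
  grid.
* Automatic quality classification is out of scope: grades are inputs
  (expert annotations or generator labels), never predictions.
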