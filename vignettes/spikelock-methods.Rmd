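---
title: "Methods: spike sorting, cluster quality and theta phase-locking in spikelock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike sorting, cluster quality and theta phase-locking in spikelock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikelock)
```

`spikelock` analyses chronic multichannel extracellular recordings:
band filtering, threshold spike detection, PCA/k-means unit isolation,
Mahalanobis cluster-quality statistics, theta phase-locking with circular
statistics, behavioral epoch statistics, and longitudinal unit tracking.
This vignette explains the models and the numerical and design choices,
and what the package's validation does and does not establish.

## Signal model and filtering

A recording is a channels × samples matrix in microvolts at a sampling
rate typically between 20,000 and 24,414 Hz; time is zero-based, and
sample *s* (1-based) sits at *(s−1)/rate* seconds. Three canonical bands
are used: LFP 0.1–300 Hz, spike band 500–3000 Hz (a 300–6000 Hz
alternative is available), and theta 4–8 Hz.

All filters are Butterworth (maximally flat passband), order 4 for
bandpass and 2 for the 58–62 Hz mains notch, applied forward–backward so
the net filter has zero phase. Zero phase is not cosmetic here: spike
phases are read off the theta-filtered trace at spike times, so any group
delay in either band would bias every phase estimate.

Numerically, the filters are designed and applied as cascaded
second-order sections (biquads), from the analytic Butterworth prototype
poles through the bilinear transform. At these sampling rates the
normalized theta band is ~3·10⁻⁴, where the expanded transfer-function
polynomial of an order-4 bandpass is singular in double precision (the
classical (b, a) representation produces NaN); the section form is exact.
Forward–backward application uses odd-reflection padding whose length
scales as 3/f<sub>low</sub> seconds so the slow corner settles; the
0.1 Hz LFP corner still produces visible edge transients on recordings of
a few seconds, which is intrinsic to the band, not the implementation.
Instantaneous phase is the angle of the analytic signal (FFT Hilbert
transform) with the convention **0° at the positive theta peak**,
increasing in time. The phase origin is a convention the package must fix
itself; published circular histograms rarely state theirs, so absolute
angles are only comparable within this convention.

## Detection and snippets

The threshold is −5 times the standard deviation of the entire
spike-band-filtered trace — the plain SD, not a robust estimate, which
means dense large spikes inflate the SD and effectively raise the
threshold; a MAD-based option exists behind `robustSd = TRUE` but is off
by default because the plain-SD rule is the reference definition.
Detection is one-sided (negative-going); each downward crossing is
localized to the trace minimum within ±0.5 ms, and later crossings within
a 1 ms dead time are suppressed. A constant trace (SD = 0) yields an
empty train rather than an error.

Snippets span 0.8 ms before to 1.6 ms after the trough (a 2.4 ms window
covering the ~2 ms extent of typical single-unit waveforms) and are
re-centred on the local trough so the minimum sits exactly at the
alignment index. Re-centring assumes a spike-band trace; when cutting
windows at known times from a raw trace (e.g. measuring amplitudes at
ground-truth times), `align = FALSE` must be used, otherwise the local
minimum of the LFP-dominated signal hijacks the alignment.

The signal-to-noise ratio is the rms over spike windows divided by the
rms over the remaining samples. The window half-width defaults to 0.5 ms,
matching the ~1 ms central lobe of the waveform; wider windows dilute the
spike rms with surrounding noise and systematically lower the ratio.

## Unit isolation and cluster quality

Features are the projections of mean-centred snippets on the top 8
principal axes. Eight dimensions is the reference feature-space size for
the quality statistics; the sign of each axis is fixed (largest-magnitude
loading positive) purely for reproducibility. k-means runs with 10 seeded
restarts, keeping the lowest within-cluster sum of squares; labels are
renumbered by decreasing cluster size so results are stable across runs.
The cluster count *k* is a per-channel user decision; `suggestK()`
reports mean silhouette widths but is never applied automatically.

For cluster *C* with *N*<sub>c</sub> member spikes, squared Mahalanobis
distances use *C*'s own mean and unbiased covariance. The L-ratio is

$$L_{ratio} = \frac{L(C)}{N_c}, \qquad
  L(C) = \sum_{i \notin C}\bigl[1 - CDF_{\chi^2, df}(MD^2_{i,C})\bigr],$$

with *df* tied to the feature dimension actually used (8 by default), and
"non-members" meaning *all* other detected spikes on the channel,
whatever label they carry. A value below 0.05 indicates good separation.
The isolation distance is the *N*<sub>c</sub>-th smallest non-member MD²;
when fewer than *N*<sub>c</sub> non-members exist it is reported as `NA`
(undefined) rather than extrapolated — a common situation when one clean
unit dominates a channel. A ridge of 10⁻⁹·trace(Σ)/d is added to the
covariance only when its condition number exceeds 10¹², so degenerate
synthetic fixtures fail soft; realistic data never touch this path.
Both statistics are invariant under affine feature maps, which the test
suite checks, and they are cross-checked against brute-force
implementations (explicit per-point linear solves; an independently coded
incomplete-gamma χ² CDF).

## Phase locking

Spike phases are nearest-sample lookups on the instantaneous-phase trace;
at ≥20 kHz and ≤8 Hz theta the lookup error is below 0.15°, so
interpolation would add complexity without precision. Units with fewer
than 25 spikes are reported with `included = FALSE` and no statistics (25
qualifies — the boundary is inclusive). The circular mean is
atan2(Σsin, Σcos) in [0°, 360°), the resultant length R̄ = |Σe^{iθ}|/n,
and the Rayleigh statistic z = nR̄² with the classical series p-value

$$p = e^{-z}\Bigl[1 + \frac{2z - z^2}{4n}
      - \frac{24z - 132z^2 + 76z^3 - 9z^4}{288 n^2}\Bigr],$$

clamped to (0, 1]. This is the approximation behind standard
circular-statistics toolboxes; its type-I error at nominal 0.05 is
verified by simulation (1000 uniform replicates at n = 100) to lie in
[0.03, 0.07]. With R̄ numerically zero (e.g. antipodal angles) the mean
direction is undefined and reported `NA`.

Theta propagation between channels is the lag maximizing the normalized
cross-correlation of two theta-filtered traces; positive delay means the
second channel lags the first.

## Behavior and longitudinal tracking

Epochs are half-open [start, end): a spike exactly at an epoch boundary
belongs to the following epoch, so repeated epochs partition time without
double counting; spikes outside all epochs are tallied under
"unassigned". The turn bias formalizes a left/right "spike ratio" as the
per-trial fraction n<sub>L</sub>/(n<sub>L</sub>+n<sub>R</sub>) with left
and right trials paired by order; trials with no spikes are excluded and
counted. LFP trends within an epoch are ordinary least squares; note that
even a pure sinusoid over an integer number of cycles has OLS slope
−12A/(2πfT²) (≈ −1.8 µV/s for A = 50 µV, f = 6 Hz, T = 3 s), not exactly
zero — a finite-window covariance effect worth remembering when
interpreting small slopes. Recording yield rounds half away from zero
(5 of 12 channels prints as 42%).

Session tracking reports, per session, the unit's amplitude, the yield,
and waveform stability (Pearson correlation of the session's
peak-normalized mean waveform with the first session's). The amplitude is
the peak-to-peak of the **mean waveform over all spikes**, after removing
the line through the window edges (slow-LFP leakage) and taking extrema
on a 3-sample moving average (sample-level noise). These choices matter
quantitatively: per-spike peak-to-peak averaged over a handful of spikes
is biased upward by the noise range — measured at ~+40% for a 24 µV
waveform under 15 µV spike-band noise with a 10-spike mean — whereas the
all-spike mean waveform recovers it to within a few percent. A 10-spike
random subsample is still used for the dispersion reported alongside.

## The synthetic generator

The generator produces the structure the analysis assumes, with ground
truth: per channel, a theta cosine (4–8 Hz, with per-channel propagation
delay), a 1/f background confined below 300 Hz (so it perturbs LFP
analysis but not spike detection), white noise, an optional 60 Hz mains
tone, and biphasic templates added at the units' spike times. Spike
trains are inhomogeneous Poisson processes simulated by thinning with
intensity

$$\lambda(t) = r \cdot g(\mathrm{epoch}(t)) \cdot
   \frac{e^{\kappa \cos(\phi(t) - \mu)}}{I_0(\kappa)},$$

where the I₀ normalization makes the von Mises phase factor average to 1
over a uniform cycle, so state gains and base rates stay interpretable;
the absolute refractory period is enforced by deleting violating spikes
(which also shrinks realized rates by a factor ≈ 1/(1 + r·refractory)
and pushes the running/standstill rate ratio slightly below its
generative value — visible in recovery tests). von Mises phase preference
is the minimal generative model for unimodal circular histograms.
Embedded spike times are snapped to the sample grid so noiseless
detection recovers them exactly.

`noiseRms` is defined as the rms of the white noise **measured in the
500–3000 Hz spike band** — the number a practitioner reads off a
single-unit trace — so the broadband white sd is inflated by
√(Nyquist/bandwidth). The noise spectrum itself (white + pink split) is a
package choice; real electrode noise is only characterized here by its
in-band rms.

Default study conditions follow the recorded system being emulated:
24,414 Hz sampling (a 20,000 Hz wireless preset is available), ~15 µV
in-band noise, theta amplitudes of order 100 µV, amplitude trajectories
such as 24 → 143 → 125 µV across weeks 1/15/33 with a fixed template
shape (the same neuron), and sortable-channel schedules like 5-of-12.
Note an interaction built into those conditions: with 15 µV in-band noise
the −5·SD threshold sits near −75 µV, so a 24 µV (or even 100 µV
peak-to-peak, after in-band attenuation of its trough) waveform is below
threshold — early-week units are genuinely undetectable at the stated
noise level, which is why amplitude-trajectory recovery is evaluated at
ground-truth spike times and why the test fixtures use units of 240–280
µV whose filtered troughs clearly clear the threshold.

## What the validation shows — and does not

The test suite validates the pipeline by parameter recovery on synthetic
data: ≥95% detection recall for strong units, ≥90% correct unit
assignment end to end, circular means within ±10° of generative preferred
phases (330°/45°), amplitude trajectories within ±15%, theta delays
within ±2 ms, Rayleigh size within [0.03, 0.07], and brute-force oracle
equality for the quality statistics; pipelines rerun bit-identically
under a fixed seed. Problem sizes were chosen for statistical power at
desk scale: 10–120 s recordings, 1–2 channels, units firing 3–8 spikes/s.

The generator omits several features of real recordings: electrode drift
and motion artifacts, overlapping-spike waveform superposition beyond
simple addition, bursting (the refractory deletion is the only ISI
structure), non-stationary noise, and biophysical waveform diversity.
Passing recovery tests therefore demonstrates correctness of the
implemented statistics under the stated generative model, not robustness
of spike sorting to everything in vivo. Template matching,
overlapping-spike resolution, drift correction, spike-field coherence and
place-field analyses are out of scope.
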