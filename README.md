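# spikelock

Spike sorting, cluster-quality statistics and theta phase-locking for
chronic multichannel extracellular recordings.

## The problem

Chronically implanted microelectrodes record a mixture of signals: slow
local field potentials (LFP, here 0.1–300 Hz) that carry population
rhythms such as the hippocampal theta oscillation (4–8 Hz), and brief
(~1–2 ms) extracellular action potentials riding on ~15 µV of noise in the
spike band (500–3000 Hz). Turning such recordings into science requires a
chain of standard but detail-sensitive steps: band filtering without phase
distortion, threshold spike detection, isolating single units from
waveform features, quantifying how clean that isolation is, relating each
unit's firing to the theta phase and to behavior, and tracking units
across weeks of recording. `spikelock` implements that chain as a tested R
package, together with a synthetic-recording generator with ground truth,
so every stage can be validated by parameter recovery.

## The statistics at the core

* **Detection.** Spikes are downward crossings of a threshold set at
  −5 × SD of the spike-band-filtered trace, localized to the local trough,
  with a 1 ms dead time.
* **Unit isolation.** Snippets (0.8 ms before to 1.6 ms after the trough)
  are projected onto their top 8 principal components and clustered by
  k-means with seeded restarts.
* **Cluster quality.** For a cluster *C* with *N*<sub>c</sub> spikes,
  squared Mahalanobis distances MD²<sub>i,C</sub> from *C*'s own mean and
  covariance give

  L(C) = Σ<sub>i∉C</sub> [1 − CDF<sub>χ²,df</sub>(MD²<sub>i,C</sub>)],  L-ratio = L(C)/N<sub>c</sub>

  with df the feature dimension (8); L-ratio < 0.05 indicates good
  separation. The isolation distance is the MD² of the
  *N*<sub>c</sub>-th closest non-member spike (undefined when fewer than
  *N*<sub>c</sub> non-members exist).
* **Phase locking.** Spike phases are looked up on the instantaneous phase
  (analytic signal; 0° at the theta peak) of the 4–8 Hz filtered LFP.
  Units with at least 25 spikes get a circular mean, resultant length
  R̄, and a Rayleigh nonuniformity test (z = nR̄², classical series
  p-value).
* **Behavior and chronic tracking.** Firing rates per behavioral epoch
  (half-open intervals), per-trial left/right spike fractions, OLS trends
  of the LFP within epochs, recording yield (percent of channels with
  sortable units), amplitude time courses and peak-normalized waveform
  similarity across sessions.

The synthetic generator produces the same structure the analysis assumes:
theta LFP with per-channel propagation delays, pink (<300 Hz) background,
spike-band white noise, optional 60 Hz mains, and units firing as
inhomogeneous Poisson processes (by thinning) with von Mises phase
preference, behavioral-state rate gains, refractory periods and biphasic
templates.

## A worked example

```r
library(spikelock)

fx  <- makeFixtures(0)            # 2-channel, 10 s synthetic set + ground truth
res <- runPipeline(fx$config, quiet = TRUE)

res$summary$yield_pct             # 100  (both channels carry sortable units)
res$channels$ch1$quality
#   cluster  n        L   L_ratio isolation_distance df
# 1       1 64 0.008325 0.0001301                 NA  8
# 2       2 58 0.109926 0.0018953              57.92  8
res$channels$ch1$phase
#     unit  n mean_deg      R     z         p included
# 1 ch1.c1 64    47.63 0.8656 47.95 3.861e-20     TRUE
# 2 ch1.c2 58   335.71 0.8933 46.28 2.176e-19     TRUE
```

Both hippocampal-channel clusters have L-ratios far below the 0.05
good-separation criterion. (Cluster 1's isolation distance is undefined —
reported `NA` — because fewer non-member spikes than members exist on the
channel.) The recovered circular means, 47.6° and 335.7°, sit within a few
degrees of the generative preferred phases (45° and 330°), and both units
are significantly phase-locked. The visual-cortex unit fires at 25.6
spikes/s while the animal runs versus 7.2 spikes/s at standstill,
recovering its generative 3× running gain within sampling error:

```r
res$channels$ch2$behavior
#     unit      label count duration_s rate_hz
# 1 ch2.c1    running   128          5    25.6
# 2 ch2.c1 standstill    36          5     7.2
```

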