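Package: spikelock
Title: Spike Sorting, Cluster Quality and Theta Phase-Locking for
    Chronic Multichannel Extracellular Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for chronic multichannel extracellular
    recordings: zero-phase band filtering of local field potentials and
    spike-band signals, threshold spike detection at -5 standard
    deviations of the filtered trace, snippet extraction,
    eight-dimensional PCA features with k-means unit isolation,
    Mahalanobis-distance cluster quality statistics (L-ratio and
    isolation distance), theta-band (4-8 Hz) phase-locking with Rayleigh
    circular statistics, behavioral epoch firing statistics, and
    longitudinal multi-session unit tracking. Includes a synthetic
    extracellular-recording generator with ground truth (von Mises
    phase-locked spike trains, theta LFP with cross-channel propagation
    delay, biphasic templates, pink and white background noise, optional
    60 Hz mains) for validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
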