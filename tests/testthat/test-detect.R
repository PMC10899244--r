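# Threshold detection, snippets, amplitudes, SNR, PCA, k-means.

fs <- 24414

test_that("detection handles degenerate traces and isolated templates", {
  expect_equal(nSpikes(detectSpikes(numeric(1000), fs)), 0L)
  expect_equal(nSpikes(detectSpikes(rep(3.3, 1000), fs)), 0L)

  # one -100 uV biphasic template on 10 uV noise: exactly one detection at
  # the template trough
  set.seed(7)
  x <- rnorm(fs, sd = 10)
  tpl <- makeTemplate(140, rate = fs)      # trough ~ -100 uV
  at <- 12000
  pre <- attr(tpl, "preSamples")
  x[at:(at + length(tpl) - 1)] <- x[at:(at + length(tpl) - 1)] + tpl
  troughIdx <- at + pre
  # brute-force oracle: the unique sub-threshold excursion is the global
  # minimum of the trace; detection must land on it
  thr <- -5 * sd(x)
  expect_equal(sum(x < thr & abs(seq_along(x) - troughIdx) > 50), 0)
  st <- detectSpikes(x, fs)
  expect_equal(nSpikes(st), 1L)
  expect_equal(spikeTimes(st), (which.min(x) - 1) / fs)
  expect_lte(abs(spikeTimes(st) - (troughIdx - 1) / fs), 0.0002)
})

test_that("false positives on pure Gaussian noise are rare", {
  for (s in 0:4) {
    set.seed(s)
    x <- bandpass(rnorm(60 * fs), spikeBand(), rate = fs)
    st <- detectSpikes(x, fs)
    expect_lt(nSpikes(st) / 60, 0.5)
  }
})

test_that("snippets are trough-aligned and recover embedded templates", {
  tpl <- makeTemplate(100, rate = fs)
  pre <- attr(tpl, "preSamples")
  x <- numeric(fs)
  at <- c(5000, 9000, 15000)
  for (a in at) x[a:(a + length(tpl) - 1)] <- tpl
  times <- (at + pre - 1) / fs
  snip <- extractSnippets(x, c(0, times), fs)      # t=0 is inside the guard
  expect_equal(attr(snip, "dropped"), 1L)
  expect_equal(nSpikes(snip), 3L)
  expect_equal(apply(waveforms(snip), 1, which.min),
               rep(preSamples(snip) + 1, 3))
  for (i in 1:3)
    expect_equal(as.numeric(waveforms(snip)[i, ]), as.numeric(tpl),
                 tolerance = 1e-6)
})

test_that("peak-to-peak amplitudes and grouping are exact on templates", {
  w100 <- makeTemplate(100, rate = fs)
  w60 <- makeTemplate(60, rate = fs)
  m <- rbind(as.numeric(w100), as.numeric(w60))
  amps <- peakToPeak(m)
  expect_equal(amps, c(100, 60), tolerance = 0.1)
  res <- peakToPeak(m, groups = c("u", "u"))
  expect_equal(res$summary$mean, 80, tolerance = 0.1)
  expect_equal(peakToPeak(matrix(numeric(0), 0, 10)), numeric(0))
})

test_that("SNR matches its definition and is scale invariant", {
  # constructed trace: noise rms 10 outside, rms 30 inside spike windows
  n <- 10000
  x <- rep(10, n)
  spikeAt <- c(2000, 6000) / 1000
  g <- round(0.001 * 1000)
  for (t in spikeAt) {
    i <- round(t * 1000) + 1
    x[(i - g):(i + g)] <- 30
  }
  expect_equal(computeSnr(x, spikeAt, rate = 1000, guard = 0.001), 3.0)
  expect_equal(computeSnr(5 * x, spikeAt, rate = 1000, guard = 0.001), 3.0)
  expect_error(computeSnr(x, numeric(0), rate = 1000), "undefined")
})

test_that("SNR exceeds 2 for 100 uV templates on 15 uV noise", {
  u <- unitSpec("ch1", baseRate = 8, amplitudeUv = 100)
  lfp <- lfpSpec(thetaAmp = 0, pinkAmp = 0)
  for (s in 0:4) {
    sim <- simulateRecording(u, lfp, duration = 10, noiseRms = 15,
                             rate = fs, seed = s)
    filt <- bandpass(channelTrace(sim$recording, 1), spikeBand(), rate = fs)
    snr <- computeSnr(filt, sim$groundTruth@spikeTimes$unit1, fs)
    expect_gt(snr, 2)
  }
})

test_that("PCA features span the snippet space with fixed signs", {
  set.seed(21)
  # points exactly in a 2-plane embedded in 40 dims
  basis <- qr.Q(qr(matrix(rnorm(40 * 2), 40)))
  X <- matrix(rnorm(100 * 2), 100) %*% t(basis)
  f <- pcaFeatures(X, d = 8)
  v <- apply(f, 2, var)
  expect_lt(sum(v[3:8]), 1e-9 * sum(v))
  expect_lte(sum(v), sum(apply(X, 2, var)) + 1e-9)
  # full-dimensional projection preserves total variance
  fFull <- pcaFeatures(X, d = 40)
  expect_equal(sum(apply(fFull, 2, var)), sum(apply(X, 2, var)),
               tolerance = 1e-9)
  # sign convention: dominant loading of each axis is positive
  rot <- attr(f, "rotation")
  for (j in 1:2)
    expect_gt(rot[which.max(abs(rot[, j])), j], 0)
  expect_error(pcaFeatures(X[1:8, ], d = 8), "more than d")

  # two distinct noiseless templates give exactly two feature points
  T1 <- as.numeric(makeTemplate(100, rate = fs))
  T2 <- as.numeric(makeTemplate(60, 0.6, 0.9, rate = fs))
  X2 <- rbind(T1, T1, T1, T1, T1, T2, T2, T2, T2, T2)
  f2 <- pcaFeatures(X2, d = 2)
  expect_equal(nrow(unique(round(f2, 6))), 2)
})

test_that("k-means separates well-separated clouds deterministically", {
  set.seed(31)
  a <- matrix(rnorm(200 * 8), 200)
  b <- sweep(matrix(rnorm(150 * 8), 150), 2, rep(10 / sqrt(8), 8), `+`)
  X <- rbind(a, b)
  truth <- rep(1:2, c(200, 150))
  lab <- kmeansCluster(X, 2, seed = 5)
  # brute-force check: labels agree with nearest generation centroid
  agree <- max(mean(lab == truth), mean(lab == 3 - truth))
  expect_equal(agree, 1)
  expect_identical(as.integer(lab), as.integer(kmeansCluster(X, 2, seed = 5)))
  expect_true(all(kmeansCluster(X, 1) == 1L))
  expect_equal(sum(table(lab)), nrow(X))           # label conservation
  expect_error(kmeansCluster(X[1:3, ], 5), "exceeds")

  sug <- suggestK(X, kMax = 4, seed = 5)
  expect_equal(attr(sug, "best"), 2)
})

test_that("detection recall is high for strong units and sorting recovers two units end to end", {
  # two units on one channel, filtered troughs well past the -5 SD
  # threshold, distinct shapes
  units <- list(
    unitSpec("ch1", baseRate = 5, amplitudeUv = 280, troughMs = 0.3,
             repolMs = 0.5),
    unitSpec("ch1", baseRate = 5, amplitudeUv = 260, troughMs = 0.5,
             repolMs = 0.8))
  lfp <- lfpSpec(thetaAmp = 100, pinkAmp = 10)
  accs <- recalls <- numeric(0)
  for (s in 0:4) {
    sim <- simulateRecording(units, lfp, duration = 20, noiseRms = 15,
                             rate = fs, seed = s)
    filt <- bandpass(channelTrace(sim$recording, 1), spikeBand(), rate = fs)
    det <- detectSpikes(filt, fs)
    gt <- sim$groundTruth@spikeTimes
    allGt <- sort(c(gt$unit1, gt$unit2))
    recall <- mean(vapply(allGt, function(t)
      any(abs(spikeTimes(det) - t) <= 5e-4), FALSE))
    recalls <- c(recalls, recall)
    snip <- extractSnippets(filt, det, fs)
    f <- pcaFeatures(snip, d = 8)
    lab <- kmeansCluster(f, 2, seed = 1)
    matchU <- vapply(spikeTimes(snip), function(t) {
      d1 <- min(abs(gt$unit1 - t)); d2 <- min(abs(gt$unit2 - t))
      if (min(d1, d2) > 5e-4) NA_integer_ else if (d1 < d2) 1L else 2L
    }, 1L)
    ok <- !is.na(matchU)
    acc <- max(mean(lab[ok] == matchU[ok]), mean(lab[ok] == 3 - matchU[ok]))
    accs <- c(accs, acc)
  }
  expect_true(all(recalls >= 0.95))
  expect_true(all(accs >= 0.9))
})
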