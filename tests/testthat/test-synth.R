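# Synthetic-data generator: geometry helper, templates, spike trains,
# recordings, session series.

test_that("electrode exposed area is the half-cylinder surface", {
  expect_equal(electrodeExposedArea(5, 7.5), pi * 2.5 * 7.5)
  # printed value for the 5 x 7.5 um opening, within rounding
  expect_equal(electrodeExposedArea(5, 7.5), 58.8, tolerance = 0.01)
  expect_equal(electrodeExposedArea(10, 7.5),
               2 * electrodeExposedArea(5, 7.5))
  expect_lt(electrodeExposedArea(5, 1e-9), 1e-7)   # degenerate height
  expect_error(electrodeExposedArea(-5, 7.5), "positive")
})

test_that("templates are biphasic, trough-aligned and scale linearly", {
  w <- makeTemplate(100, rate = 24414)
  expect_equal(max(w) - min(w), 100, tolerance = 1)
  expect_equal(which.min(w), attr(w, "preSamples") + 1)
  expect_lt(min(w), 0)
  expect_gt(max(w), 0)
  expect_true(which.max(w) > which.min(w))          # rebound after trough
  w2 <- makeTemplate(200, rate = 24414)
  expect_equal(as.numeric(w2), as.numeric(2 * w), tolerance = 1e-9)
  expect_error(makeTemplate(100, troughMs = 3, rate = 24414), "window")
})

test_that("homogeneous spike trains have Poisson-scale counts and obey the refractory period", {
  r <- 10; T <- 60
  u <- unitSpec("ch1", baseRate = r, refractorySec = 0.002)
  for (s in 0:9) {
    st <- simulateSpikeTrain(u, duration = T, seed = s)
    # Poisson mean r*T shrunk slightly by refractory deletion
    expect_lt(abs(length(st) - r * T), 4 * sqrt(r * T))
    if (length(st) > 1) expect_gte(min(diff(st)), 0.002)
  }
})

test_that("phase-locked trains concentrate at the preferred phase", {
  phaseFun <- function(t) (360 * 6 * t) %% 360
  u <- unitSpec("ch1", baseRate = 12, preferredPhaseDeg = 330, kappa = 8)
  st <- simulateSpikeTrain(u, phaseFun, duration = 90, seed = 2)
  expect_gt(length(st), 500)
  expect_lt(angDiff(circMeanDeg(phaseFun(st)), 330), 5)
  # independent oracle: rejection-sampled von Mises has the same mean
  ora <- oracleVonMises(2000, 330, 8, seed = 2)
  expect_lt(angDiff(circMeanDeg(ora), circMeanDeg(phaseFun(st))), 5)
})

test_that("von Mises phase factor is normalized to unit mean", {
  for (k in c(0.5, 2, 4, 8)) {
    grid <- seq(0, 360, length.out = 100001)[-100001]
    f <- exp(k * cos((grid - 123) * pi / 180)) / besselI(k, 0)
    expect_equal(mean(f), 1, tolerance = 1e-3)
  }
})

test_that("unit-free recordings carry the configured spike-band noise", {
  lfp <- lfpSpec(thetaFreq = 6, thetaAmp = 100, pinkAmp = 10)
  sim <- simulateRecording(list(), lfp, duration = 10, noiseRms = 15,
                           rate = 24414, seed = 4, channelIds = "ch1")
  filt <- bandpass(channelTrace(sim$recording, 1), spikeBand(), rate = 24414)
  expect_equal(rmsOf(filt), 15, tolerance = 0.10)
})

test_that("noiseless embedding puts detectable troughs exactly at ground truth", {
  u <- unitSpec("ch1", baseRate = 5, amplitudeUv = 100)
  lfp <- lfpSpec(thetaAmp = 0, pinkAmp = 0)
  sim <- simulateRecording(u, lfp, duration = 5, noiseRms = 0,
                           rate = 24414, seed = 5)
  tr <- channelTrace(sim$recording, 1)
  gt <- sim$groundTruth@spikeTimes$unit1
  det <- detectSpikes(tr, 24414)   # raw trace is template-only here
  expect_equal(spikeTimes(det), gt)
})

test_that("configured theta propagation delay appears in the cross-correlation", {
  lfp <- lfpSpec(thetaFreq = 6, thetaAmp = 100, delaysSec = c(0, 0.02),
                 pinkAmp = 0)
  sim <- simulateRecording(list(), lfp, duration = 10, noiseRms = 0,
                           rate = 24414, seed = 6,
                           channelIds = c("a", "b"))
  d <- thetaDelay(channelTrace(sim$recording, "a"),
                  channelTrace(sim$recording, "b"), 24414, maxLag = 0.05)
  expect_lt(abs(d - 0.02), 1.5 / 24414)
})

test_that("the generator is deterministic and validates its configuration", {
  u <- unitSpec("ch1", baseRate = 5)
  a <- simulateRecording(u, duration = 2, seed = 9, noiseRms = 15)
  b <- simulateRecording(u, duration = 2, seed = 9, noiseRms = 15)
  expect_identical(voltages(a$recording), voltages(b$recording))
  expect_identical(a$groundTruth@spikeTimes, b$groundTruth@spikeTimes)
  expect_error(
    simulateRecording(unitSpec("nope", 5), channelIds = "ch1",
                      duration = 1),
    "unknown channel")
})

test_that("session series follow the amplitude trajectory and channel schedule", {
  units <- list(unitSpec("ch1", baseRate = 5, kappa = 0),
                unitSpec("ch2", baseRate = 5, kappa = 0))
  traj <- c(24, 143, 125)
  ser <- simulateSessionSeries(
    units, weeks = c(1, 15, 33), amplitudeTrajectory = traj,
    sortableChannels = list("ch1", c("ch1", "ch2"), c("ch1", "ch2")),
    channelIds = c("ch1", "ch2"), duration = 4, noiseRms = 15, seed = 1)
  for (w in 1:3) {
    gt <- ser$sessions[[w]]$groundTruth
    for (tpl in gt@templates)
      expect_equal(max(tpl) - min(tpl), traj[w], tolerance = 0.01 * traj[w])
  }
  # week 1: only the sortable channel carries units
  expect_equal(unname(ser$sessions[[1]]$groundTruth@unitChannels), "ch1")
  expect_equal(length(ser$sessions[[2]]$groundTruth@spikeTimes), 2)
  expect_error(
    simulateSessionSeries(units, weeks = 1:2, amplitudeTrajectory = 1,
                          channelIds = c("ch1", "ch2")),
    "one entry per week")
})
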