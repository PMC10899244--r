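# Behavioral epoch statistics and chronic-session tracking.

test_that("epoch rates use half-open windows and conserve counts", {
  ev <- eventTable(c("running", "standstill"), c(0, 2), c(2, 4))
  st <- c(0.1, 0.5, 1.0, 1.5, 1.9, 1.99, 2.0, 3.0, 4.5)
  es <- epochStats(st, ev)
  run <- es[es$label == "running", ]
  stand <- es[es$label == "standstill", ]
  una <- es[es$label == "unassigned", ]
  expect_equal(run$count, 6)
  expect_equal(run$rate_hz, 3)
  expect_equal(stand$count, 2)               # t = 2.0 joins the next epoch
  expect_equal(una$count, 1)
  expect_equal(run$count + stand$count + una$count, length(st))

  # 10 spikes in a 2 s epoch = 5 spikes/s
  es2 <- epochStats(seq(0.05, 1.95, length.out = 10),
                    eventTable("running", 0, 2))
  expect_equal(es2$rate_hz[1], 5)
})

test_that("state-gain modulation is recovered in epoch rates", {
  ev <- eventTable(rep(c("running", "standstill"), 10),
                   seq(0, 95, by = 5), seq(5, 100, by = 5))
  u <- unitSpec("ch1", baseRate = 4, stateGain = c(running = 4))
  ratios <- vapply(0:4, function(s) {
    st <- simulateSpikeTrain(u, events = ev, duration = 100, seed = s)
    es <- epochStats(st, ev)
    es$rate_hz[es$label == "running"] / es$rate_hz[es$label == "standstill"]
  }, 0)
  expect_true(all(ratios >= 3 & ratios <= 5))
})

test_that("turn bias is a paired per-trial left fraction", {
  left <- eventTable(rep("left", 3), c(0, 10, 20), c(2, 12, 22))
  right <- eventTable(rep("right", 3), c(5, 15, 25), c(7, 17, 27))
  sym <- turnBias(c(0.5, 5.5, 10.5, 15.5, 20.5, 25.5), left, right)
  expect_equal(sym$mean, 0.5)
  allLeft <- turnBias(c(0.5, 1, 10.5, 20.5), left, right)
  expect_equal(allLeft$mean, 1.0)
  # empty trials are excluded and reported
  some <- turnBias(c(0.5, 5.5), left, right)
  expect_equal(some$nTrials, 1)
  expect_equal(some$nEmpty, 2)
  expect_error(turnBias(numeric(0), left, right), "undefined")
  expect_error(turnBias(1, left[1:2, ], right), "paired")

  # swapping left and right maps the fraction to its complement
  asym <- turnBias(c(0.5, 1, 5.5, 10.5, 20.5, 25.5), left, right)
  swap <- turnBias(c(0.5, 1, 5.5, 10.5, 20.5, 25.5), right, left)
  expect_equal(swap$mean, 1 - asym$mean)
})

test_that("a 3:1 generative left:right ratio yields mean fraction above 0.6", {
  labs <- rep(c("left", "right"), 5)
  ev <- eventTable(labs, seq(0, 18, by = 2), seq(2, 20, by = 2))
  left <- ev[ev$label == "left", ]
  right <- ev[ev$label == "right", ]
  u <- unitSpec("ch1", baseRate = 6, stateGain = c(left = 3, right = 1))
  hits <- vapply(0:9, function(s) {
    st <- simulateSpikeTrain(u, events = ev, duration = 20, seed = s)
    turnBias(st, left, right)$mean > 0.6
  }, FALSE)
  expect_gte(sum(hits), 9)
})

test_that("LFP trend slopes fit exactly and detect injected drift", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ramp <- 100 - 10 * t
  fit <- lfpTrendSlope(ramp, fs, 1, 3)
  expect_equal(fit$slope, -10, tolerance = 1e-6)
  # a sinusoid over integer cycles has near-zero slope; the exact OLS
  # value is -12 A / (2 pi f T^2), about -1.8 uV/s here
  sine <- 50 * sin(2 * pi * 6 * t)
  expect_lt(abs(lfpTrendSlope(sine, fs, 0, 3)$slope), 2)
  expect_error(lfpTrendSlope(ramp, fs, 1, 1.0005), "fewer than 2")

  # injected negative drift on a theta background is always negative
  for (s in 0:9) {
    sim <- simulateRecording(list(), lfpSpec(thetaAmp = 50, pinkAmp = 5),
                             duration = 3, noiseRms = 10, rate = 2000,
                             seed = s, channelIds = "ch1")
    x <- channelTrace(sim$recording, 1) - 20 * seq(0, 3 - 1 / 2000,
                                                   by = 1 / 2000)
    expect_lt(lfpTrendSlope(x, 2000, 0.2, 2.8)$slope, 0)
  }
})

test_that("recording yield rounds half away from zero and stays bounded", {
  expect_identical(recordingYield(5, 12), 42L)
  expect_identical(recordingYield(12, 12), 100L)
  expect_identical(recordingYield(0, 12), 0L)
  expect_identical(recordingYield(8, 12), 67L)     # 66.7 rounds up
  # monotone in nSortable
  ys <- vapply(0:12, recordingYield, 0L, nChannels = 12)
  expect_true(all(diff(ys) >= 0))
  expect_error(recordingYield(13, 12), "nSortable")
  expect_error(recordingYield(1, 0), "nChannels")
})

test_that("session tracking reports amplitude, yield and waveform stability", {
  fs <- 24414
  tpl <- makeTemplate(100, rate = fs)
  mk <- function(scale, n = 30) {
    w <- matrix(rep(as.numeric(tpl) * scale, n), n, byrow = TRUE)
    spikelock:::SnippetArray(w, attr(tpl, "preSamples"),
                             attr(tpl, "postSamples"), fs,
                             seq_len(n) / 10)
  }
  sessions <- list(
    list(week = 1, snippets = mk(1), nSortable = 5, nChannels = 12),
    list(week = 15, snippets = mk(2), nSortable = 12, nChannels = 12),
    list(week = 33, snippets = NULL, nSortable = 0, nChannels = 12))
  tk <- trackSessions(sessions)
  expect_equal(tk$yield_pct, c(42L, 100L, 0L))
  # scaling leaves the normalized-waveform similarity at 1
  expect_equal(tk$similarity[1:2], c(1, 1), tolerance = 1e-9)
  expect_equal(tk$mean_amp_uv[2] / tk$mean_amp_uv[1], 2, tolerance = 1e-6)
  expect_true(is.na(tk$mean_amp_uv[3]))
})

test_that("the 24/143/125 uV amplitude trajectory is recovered across sessions", {
  units <- list(unitSpec("ch10", baseRate = 8, amplitudeUv = 100,
                         kappa = 0))
  traj <- c(24, 143, 125)
  ser <- simulateSessionSeries(units, weeks = c(1, 15, 33),
                               amplitudeTrajectory = traj, duration = 60,
                               noiseRms = 15, seed = 2)
  sessions <- lapply(seq_along(ser$sessions), function(i) {
    ses <- ser$sessions[[i]]
    snip <- extractSnippets(channelTrace(ses$recording, 1),
                            ses$groundTruth@spikeTimes$unit1,
                            samplingRate(ses$recording), align = FALSE)
    list(week = ser$manifest$week[i], snippets = snip, nSortable = 1,
         nChannels = 1)
  })
  tk <- trackSessions(sessions)
  expect_true(all(abs(tk$mean_amp_uv - traj) / traj < 0.15))
  expect_equal(order(tk$mean_amp_uv), c(1, 3, 2))  # 1 < 33 < 15 weeks
  expect_true(all(tk$similarity > 0.9))
})
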