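# Synthetic extracellular recordings with ground truth.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes: a 4-8 Hz theta LFP with per-channel propagation delay, single
# units firing as inhomogeneous Poisson processes whose phase preference is
# von Mises around a preferred theta angle, behavioral-state rate gains,
# biphasic spike templates, pink (<300 Hz) background, spike-band white
# noise, and optional 60 Hz mains.

#' Exposed electrode surface area
#'
#' Area of the exposed half-cylinder electrode tip: a cylinder of diameter
#' `width` with exposed height `height`, of which half the lateral surface
#' faces the tissue, \eqn{\pi (width/2) \cdot height}.
#'
#' @param width electrode line width in micrometres (cylinder diameter).
#' @param height exposed height in micrometres.
#' @return area in square micrometres.
#' @examples
#' electrodeExposedArea(5, 7.5)  # ~58.9 um^2
#' @export
electrodeExposedArea <- function(width, height) {
  if (!is.finite(width) || width <= 0 || !is.finite(height) || height <= 0)
    stop("electrode dimensions must be positive")
  pi * (width / 2) * height
}

#' Biphasic spike template
#'
#' A negative trough followed by a positive repolarization bump, sampled at
#' `rate`, with the trough exactly at the alignment index
#' `preSamples + 1` and peak-to-peak amplitude equal to `amplitudeUv`.
#'
#' @param amplitudeUv peak-to-peak amplitude, microvolts.
#' @param troughMs width (FWHM-like scale) of the negative trough, ms.
#' @param repolMs width of the positive repolarization, ms.
#' @param rate sampling rate, Hz.
#' @param preMs,postMs window before/after the trough, ms (default 0.8/1.6,
#'   a 2.4 ms window spanning the ~2 ms waveforms typical of single units).
#' @return numeric waveform vector (microvolts) with attributes
#'   `preSamples` and `postSamples`.
#' @export
makeTemplate <- function(amplitudeUv, troughMs = 0.4, repolMs = 0.6,
                         rate = 24414, preMs = 0.8, postMs = 1.6) {
  if (amplitudeUv <= 0) stop("amplitude must be positive")
  if (troughMs <= 0 || repolMs <= 0) stop("widths must be positive")
  if (troughMs / 2 > preMs || troughMs / 2 + repolMs > postMs)
    stop("template widths exceed the snippet window")
  pre <- round(preMs / 1000 * rate)
  post <- round(postMs / 1000 * rate)
  n <- pre + post + 1
  tMs <- (seq_len(n) - (pre + 1)) / rate * 1000
  sigT <- troughMs / 2.355                       # FWHM -> gaussian sigma
  sigR <- repolMs / 2.355
  dR <- troughMs / 2 + repolMs / 2               # rebound centre after trough
  w <- -exp(-(tMs / sigT)^2 / 2) + 0.4 * exp(-((tMs - dR) / sigR)^2 / 2)
  w <- w * amplitudeUv / (max(w) - min(w))
  stopifnot(which.min(w) == pre + 1)
  structure(w, preSamples = pre, postSamples = post)
}

#' Single-unit generative parameters
#'
#' @param channelId channel the unit lives on.
#' @param baseRate mean firing rate, spikes/s.
#' @param amplitudeUv template peak-to-peak amplitude, microvolts.
#' @param troughMs,repolMs template shape widths, ms.
#' @param preferredPhaseDeg preferred theta phase, degrees in `[0, 360)`.
#' @param kappa von Mises concentration (>= 0; 0 = no phase preference).
#' @param stateGain named numeric vector of rate multipliers per epoch
#'   label (epochs not listed get gain 1).
#' @param refractorySec absolute refractory period, s.
#' @return classed list of generative parameters.
#' @export
unitSpec <- function(channelId, baseRate, amplitudeUv = 100, troughMs = 0.4,
                     repolMs = 0.6, preferredPhaseDeg = 0, kappa = 0,
                     stateGain = numeric(0), refractorySec = 0.002) {
  if (baseRate < 0) stop("baseRate must be >= 0")
  if (kappa < 0) stop("kappa must be >= 0")
  if (refractorySec <= 0) stop("refractorySec must be > 0")
  if (amplitudeUv <= 0) stop("amplitudeUv must be > 0")
  structure(list(channelId = as.character(channelId), baseRate = baseRate,
                 amplitudeUv = amplitudeUv, troughMs = troughMs,
                 repolMs = repolMs,
                 preferredPhaseDeg = preferredPhaseDeg %% 360,
                 kappa = kappa, stateGain = stateGain,
                 refractorySec = refractorySec),
            class = "unitSpec")
}

#' LFP generative parameters
#'
#' @param thetaFreq theta frequency, Hz, in `[4, 8]`.
#' @param thetaAmp theta amplitude, microvolts.
#' @param delaysSec per-channel propagation delay of the theta wave, s
#'   (named by channel or recycled in channel order).
#' @param pinkAmp rms of the 1/f background (confined below 300 Hz so it
#'   perturbs LFP analysis but not spike detection), microvolts.
#' @param mainsAmp amplitude of a 60 Hz mains component, microvolts
#'   (0 = off).
#' @return classed list.
#' @export
lfpSpec <- function(thetaFreq = 6, thetaAmp = 100, delaysSec = 0,
                    pinkAmp = 10, mainsAmp = 0) {
  if (thetaFreq < 4 || thetaFreq > 8)
    stop("thetaFreq must lie in the 4-8 Hz theta band")
  if (any(!is.finite(delaysSec))) stop("delays must be finite")
  structure(list(thetaFreq = thetaFreq, thetaAmp = thetaAmp,
                 delaysSec = delaysSec, pinkAmp = pinkAmp,
                 mainsAmp = mainsAmp),
            class = "lfpSpec")
}

# von Mises phase-modulation factor, normalized to average 1 over a
# uniform phase cycle: exp(k cos(theta - mu)) / I0(k)
vonMisesFactor <- function(phaseDeg, muDeg, kappa) {
  if (kappa == 0) return(rep(1, length(phaseDeg)))
  exp(kappa * cos((phaseDeg - muDeg) * pi / 180)) /
    besselI(kappa, 0, expon.scaled = FALSE)
}

epochGainFun <- function(stateGain, events) {
  if (is.null(events) || nrow(events) == 0 || length(stateGain) == 0)
    return(function(t) rep(1, length(t)))
  function(t) {
    g <- rep(1, length(t))
    for (i in seq_len(nrow(events))) {
      lab <- events$label[i]
      if (lab %in% names(stateGain)) {
        inEpoch <- t >= events$t_start[i] & t < events$t_end[i]
        g[inEpoch] <- stateGain[[lab]]
      }
    }
    g
  }
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson process by thinning with intensity
#' \deqn{\lambda(t) = r \, g(epoch(t)) \, e^{\kappa \cos(\phi(t)-\mu)} / I_0(\kappa)}
#' followed by deletion of spikes violating the absolute refractory
#' period.  The \eqn{I_0(\kappa)} normalization makes the phase factor
#' average to 1 over a uniform phase cycle, so the long-run rate stays
#' `baseRate * gain`.
#'
#' @param unit a [unitSpec()].
#' @param thetaPhase function of time (s) returning theta phase in degrees.
#' @param events event data.frame for state gains, or `NULL`.
#' @param duration recording duration, s.
#' @param seed RNG seed.
#' @return numeric vector of spike times, strictly increasing (possibly
#'   empty).
#' @export
simulateSpikeTrain <- function(unit, thetaPhase = NULL, events = NULL,
                               duration, seed = 1) {
  stopifnot(inherits(unit, "unitSpec"), duration > 0)
  gainFun <- epochGainFun(unit$stateGain, events)
  maxGain <- max(1, unit$stateGain)
  vmMax <- if (unit$kappa == 0) 1 else
    exp(unit$kappa) / besselI(unit$kappa, 0)
  lambdaMax <- unit$baseRate * maxGain * vmMax
  if (lambdaMax == 0) return(numeric(0))
  withSeed(seed, {
    nCand <- stats::rpois(1, lambdaMax * duration)
    cand <- sort(stats::runif(nCand, 0, duration))
    lam <- unit$baseRate * gainFun(cand)
    if (unit$kappa > 0 && !is.null(thetaPhase))
      lam <- lam * vonMisesFactor(thetaPhase(cand), unit$preferredPhaseDeg,
                                  unit$kappa)
    keep <- stats::runif(nCand) < lam / lambdaMax
    times <- cand[keep]
    # absolute refractory period: delete violators
    if (length(times) > 1) {
      ok <- logical(length(times))
      last <- -Inf
      for (i in seq_along(times)) {
        if (times[i] - last >= unit$refractorySec) {
          ok[i] <- TRUE
          last <- times[i]
        }
      }
      times <- times[ok]
    }
    times
  })
}

# 1/f-shaped background confined below fMax, scaled to rms `amp`
pinkNoise <- function(n, rate, amp, fMax = 300) {
  if (amp <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f[f > rate / 2] <- rate - f[f > rate / 2]       # fold to physical freq
  shape <- ifelse(f > 0.5 & f <= fMax, 1 / sqrt(f), 0)
  x <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * amp / s
}

thetaPhaseFunFor <- function(lfp, delay) {
  f <- lfp$thetaFreq
  function(t) (360 * f * (t - delay)) %% 360
}

#' Simulate a multichannel recording with ground truth
#'
#' Each channel is the sum of a delayed theta sinusoid, a 1/f background
#' below 300 Hz, white noise whose spike-band (500-3000 Hz) rms equals
#' `noiseRms`, an optional 60 Hz mains component, and the units' biphasic
#' templates added at their ground-truth spike times.  Identical seed and
#' configuration reproduce the recording bit for bit.
#'
#' @param units list of [unitSpec()]s (may be empty).
#' @param lfp an [lfpSpec()].
#' @param events event data.frame or `NULL`.
#' @param duration duration, s.
#' @param noiseRms spike-band rms of the white noise, microvolts.
#' @param rate sampling rate, Hz (default 24414; use 20000 to mirror a
#'   wireless acquisition unit).
#' @param seed RNG seed.
#' @param channelIds,regions channel layout; default derived from the units.
#' @return list with elements `recording` ([Recording-class]) and
#'   `groundTruth` ([GroundTruth-class]).
#' @export
simulateRecording <- function(units = list(), lfp = lfpSpec(), events = NULL,
                              duration = 10, noiseRms = 15, rate = 24414,
                              seed = 1, channelIds = NULL, regions = NULL) {
  if (inherits(units, "unitSpec")) units <- list(units)
  if (is.null(channelIds)) {
    channelIds <- unique(vapply(units, `[[`, "", "channelId"))
    if (!length(channelIds)) channelIds <- "ch1"
  }
  if (is.null(regions)) regions <- rep("unknown", length(channelIds))
  unitCh <- vapply(units, `[[`, "", "channelId")
  bad <- setdiff(unitCh, channelIds)
  if (length(bad))
    stop("unit references unknown channel: ", paste(bad, collapse = ", "))
  nCh <- length(channelIds)
  n <- round(duration * rate)
  delays <- rep(lfp$delaysSec, length.out = nCh)
  # white-noise scale: requested rms is measured in the 500-3000 Hz spike
  # band, so the broadband sd is inflated by sqrt(nyquist / bandwidth)
  whiteSd <- noiseRms * sqrt((rate / 2) / 2500)
  tAx <- (seq_len(n) - 1) / rate

  samples <- matrix(0, nCh, n)
  gtTimes <- list()
  gtChannels <- character(0)
  templates <- list()
  withSeed(seed, {
    for (c in seq_len(nCh)) {
      theta <- lfp$thetaAmp * cos(2 * pi * lfp$thetaFreq * (tAx - delays[c]))
      x <- theta + pinkNoise(n, rate, lfp$pinkAmp)
      if (noiseRms > 0) x <- x + stats::rnorm(n, sd = whiteSd)
      if (lfp$mainsAmp > 0) x <- x + lfp$mainsAmp * sin(2 * pi * 60 * tAx)
      samples[c, ] <- x
    }
    for (ui in seq_along(units)) {
      u <- units[[ui]]
      c <- match(u$channelId, channelIds)
      phaseFun <- thetaPhaseFunFor(lfp, delays[c])
      unitSeed <- sample.int(.Machine$integer.max, 1)
      st <- simulateSpikeTrain(u, phaseFun, events, duration,
                               seed = unitSeed)
      # snap to the sample grid so embedded troughs coincide exactly with
      # the recorded ground-truth times
      st <- unique(pmin(pmax(round(st * rate), 1), n - 1)) / rate
      tpl <- makeTemplate(u$amplitudeUv, u$troughMs, u$repolMs, rate)
      pre <- attr(tpl, "preSamples")
      for (t in st) {
        i0 <- round(t * rate) + 1 - pre        # trough lands at round(t*rate)+1
        idx <- i0:(i0 + length(tpl) - 1)
        inb <- idx >= 1 & idx <= n
        samples[c, idx[inb]] <- samples[c, idx[inb]] + tpl[inb]
      }
      nm <- paste0("unit", ui)
      gtTimes[[nm]] <- st
      gtChannels[nm] <- u$channelId
      templates[[nm]] <- tpl
    }
  })
  rec <- Recording(samples, rate, channelIds, regions)
  gt <- new("GroundTruth", spikeTimes = gtTimes, unitChannels = gtChannels,
            units = units, lfp = lfp, noiseRms = noiseRms,
            templates = templates)
  list(recording = rec, groundTruth = gt)
}

#' Simulate a chronic multi-week session series
#'
#' One recording per week.  Unit amplitudes follow `amplitudeTrajectory`
#' while the template shape stays fixed across weeks (the same neuron);
#' units are present only on that week's sortable channels.
#'
#' @param units list of [unitSpec()]s giving shape, rate and channel of
#'   every potential unit (amplitudes are overridden per week).
#' @param weeks numeric vector of session times (weeks, non-decreasing).
#' @param amplitudeTrajectory peak-to-peak amplitude (microvolts) per week;
#'   same length as `weeks`.
#' @param sortableChannels list (one element per week) of channel ids that
#'   carry units that week; default all channels every week.
#' @param channelIds,regions full channel layout.
#' @param lfp,events,duration,noiseRms,rate as in [simulateRecording()].
#' @param seed RNG seed; per-week child seeds are derived from it.
#' @param dir if non-`NULL`, recordings and events are written there and the
#'   manifest carries their paths.
#' @return list with `manifest` (data.frame: `week`, `recording`, `events`),
#'   and `sessions`, a per-week list of `recording`, `groundTruth`,
#'   `sortableChannels`.
#' @export
simulateSessionSeries <- function(units, weeks, amplitudeTrajectory,
                                  sortableChannels = NULL,
                                  channelIds = NULL, regions = NULL,
                                  lfp = lfpSpec(), events = NULL,
                                  duration = 10, noiseRms = 15,
                                  rate = 24414, seed = 1, dir = NULL) {
  if (length(amplitudeTrajectory) != length(weeks))
    stop("amplitudeTrajectory must have one entry per week")
  if (is.unsorted(weeks))
    stop("weeks must be non-decreasing")
  if (is.null(channelIds))
    channelIds <- unique(vapply(units, `[[`, "", "channelId"))
  if (is.null(sortableChannels))
    sortableChannels <- rep(list(channelIds), length(weeks))
  if (length(sortableChannels) != length(weeks))
    stop("sortableChannels must have one entry per week")
  sessions <- vector("list", length(weeks))
  manifest <- data.frame(week = weeks,
                         recording = NA_character_,
                         events = NA_character_,
                         stringsAsFactors = FALSE)
  for (w in seq_along(weeks)) {
    sortable <- sortableChannels[[w]]
    wkUnits <- lapply(units, function(u) {
      u$amplitudeUv <- amplitudeTrajectory[w]
      u
    })
    wkUnits <- Filter(function(u) u$channelId %in% sortable, wkUnits)
    sim <- simulateRecording(wkUnits, lfp, events, duration, noiseRms,
                             rate, seed = childSeed(seed, w),
                             channelIds = channelIds, regions = regions)
    sessions[[w]] <- list(recording = sim$recording,
                          groundTruth = sim$groundTruth,
                          sortableChannels = sortable)
    if (!is.null(dir)) {
      stem <- file.path(dir, sprintf("week%03d", weeks[w]))
      writeRecording(sim$recording, stem)
      manifest$recording[w] <- paste0(stem, ".bin")
      if (!is.null(events)) {
        ep <- file.path(dir, sprintf("week%03d_events.tsv", weeks[w]))
        writeEvents(events, ep)
        manifest$events[w] <- ep
      }
    }
  }
  list(manifest = manifest, sessions = sessions)
}
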