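# Threshold spike detection, snippet extraction, amplitude and SNR.

#' Detection parameters
#'
#' @param thresholdMultiplier negative multiplier of the trace standard
#'   deviation; the threshold is `thresholdMultiplier * SD(trace)`
#'   (default -5).
#' @param deadTime minimum spacing between accepted threshold crossings, s.
#' @param preWindow,postWindow snippet window before/after the trough, s.
#' @param robustSd use a median-based (MAD) scale estimate instead of the
#'   plain standard deviation.  Off by default: the detection rule is
#'   defined on the plain SD of the whole filtered trace.
#' @return classed parameter list.
#' @export
detectionParams <- function(thresholdMultiplier = -5, deadTime = 0.001,
                            preWindow = 0.0008, postWindow = 0.0016,
                            robustSd = FALSE) {
  if (thresholdMultiplier >= 0)
    stop("thresholdMultiplier must be negative (downward threshold)")
  if (deadTime <= 0 || preWindow <= 0 || postWindow <= 0)
    stop("deadTime and windows must be positive")
  structure(list(thresholdMultiplier = thresholdMultiplier,
                 deadTime = deadTime, preWindow = preWindow,
                 postWindow = postWindow, robustSd = robustSd),
            class = "detectionParams")
}

#' Threshold spike detection
#'
#' Detects negative-going spikes on a spike-band-filtered trace.  The
#' threshold is `thresholdMultiplier` times the standard deviation of the
#' whole trace (default -5 SD).  Each downward crossing is localized to the
#' trace minimum within +-0.5 ms; later crossings within `deadTime` of an
#' accepted one are suppressed.
#'
#' @param x numeric vector (spike-band filtered, microvolts) or a
#'   single-channel [Recording-class].
#' @param rate sampling rate, Hz (taken from a recording input).
#' @param params a [detectionParams()].
#' @param channelId label carried into the returned train.
#' @return A [SpikeTrain-class].  A constant trace (SD = 0) yields an empty
#'   train.
#' @export
detectSpikes <- function(x, rate = NULL, params = detectionParams(),
                         channelId = "ch1") {
  if (is(x, "Recording")) {
    stopifnot(nrow(x@samples) == 1)
    rate <- x@rate
    channelId <- x@channelIds[1]
    x <- x@samples[1, ]
  }
  if (is.null(rate)) stop("rate is required for a plain vector")
  s <- if (params$robustSd) stats::mad(x) else stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(SpikeTrain(channelId, numeric(0)))     # degenerate constant trace
  thr <- params$thresholdMultiplier * s
  below <- x < thr
  crossings <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(crossings)) return(SpikeTrain(channelId, numeric(0)))
  half <- round(0.0005 * rate)
  deadSamp <- params$deadTime * rate
  n <- length(x)
  troughs <- integer(0)
  lastCross <- -Inf
  for (cr in crossings) {
    if (cr - lastCross < deadSamp) next
    lastCross <- cr
    lo <- max(1L, cr - half)
    hi <- min(n, cr + half)
    troughs <- c(troughs, lo - 1L + which.min(x[lo:hi]))
  }
  troughs <- sort(unique(troughs))
  SpikeTrain(channelId, (troughs - 1) / rate)
}

#' Extract aligned waveform snippets
#'
#' Cuts a window of `preWindow` before and `postWindow` after each spike
#' time and re-centres it on the local trough (within +-0.5 ms of the given
#' time) so that every snippet's minimum sits at column `preSamples + 1`.
#' Spikes too close to the trace edges are dropped; the count of dropped
#' spikes is attached as attribute `"dropped"`.
#'
#' @inheritParams detectSpikes
#' @param spikeTimes spike times in seconds (or a [SpikeTrain-class]).
#' @param align re-centre each window on the local trough (default).  Turn
#'   off when cutting windows at known (ground-truth) times from a trace
#'   that is not spike-band filtered, where the local minimum would be a
#'   noise or LFP feature rather than the spike trough.
#' @return A [SnippetArray-class].
#' @export
extractSnippets <- function(x, spikeTimes, rate = NULL,
                            params = detectionParams(), align = TRUE) {
  if (is(x, "Recording")) {
    stopifnot(nrow(x@samples) == 1)
    rate <- x@rate
    x <- x@samples[1, ]
  }
  if (is(spikeTimes, "SpikeTrain")) spikeTimes <- spikeTimes@spikeTimes
  if (is.null(rate)) stop("rate is required for a plain vector")
  pre <- round(params$preWindow * rate)
  post <- round(params$postWindow * rate)
  half <- round(0.0005 * rate)
  n <- length(x)
  centres <- integer(0)
  kept <- numeric(0)
  dropped <- 0L
  for (t in spikeTimes) {
    i <- round(t * rate) + 1L
    if (align) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      i <- lo - 1L + which.min(x[lo:hi])          # re-centre on the trough
    }
    if (i - pre < 1L || i + post > n) {
      dropped <- dropped + 1L
      next
    }
    centres <- c(centres, i)
    kept <- c(kept, (i - 1) / rate)
  }
  wf <- if (length(centres))
    t(vapply(centres, function(i) x[(i - pre):(i + post)],
             numeric(pre + post + 1))) else
    matrix(numeric(0), 0, pre + post + 1)
  out <- SnippetArray(wf, pre, post, rate, kept)
  attr(out, "dropped") <- dropped
  out
}

#' Peak-to-peak spike amplitudes
#'
#' Per-snippet `max - min` in microvolts, with optional group summaries.
#'
#' @param snippets a [SnippetArray-class] (or waveform matrix).
#' @param groups optional factor (one level per snippet); when given, a
#'   data.frame of per-group `n`, `mean`, `sd` is returned alongside.
#' @return numeric vector of amplitudes, or when `groups` is given a list
#'   with `amplitudes` and `summary`.
#' @export
peakToPeak <- function(snippets, groups = NULL) {
  wf <- if (is(snippets, "SnippetArray")) snippets@waveforms else snippets
  if (nrow(wf) == 0) {
    amps <- numeric(0)
  } else {
    amps <- apply(wf, 1, max) - apply(wf, 1, min)
  }
  if (is.null(groups)) return(amps)
  groups <- factor(groups)
  summary <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(amps, groups, mean)),
    sd = as.numeric(tapply(amps, groups, stats::sd)),
    stringsAsFactors = FALSE)
  list(amplitudes = amps, summary = summary)
}

#' Signal-to-noise ratio of a spike-band trace
#'
#' Ratio of the rms over the concatenated spike windows (+-`guard` seconds
#' around each spike time) to the rms over all remaining samples.
#'
#' @inheritParams detectSpikes
#' @param spikeTimes spike times, s (or a [SpikeTrain-class]).
#' @param guard half-width of the spike window, s; the 0.5 ms default
#'   matches the ~1 ms central lobe of extracellular spike waveforms.
#' @return dimensionless ratio.
#' @export
computeSnr <- function(x, spikeTimes, rate = NULL, guard = 0.0005) {
  if (is(x, "Recording")) {
    stopifnot(nrow(x@samples) == 1)
    rate <- x@rate
    x <- x@samples[1, ]
  }
  if (is(spikeTimes, "SpikeTrain")) spikeTimes <- spikeTimes@spikeTimes
  if (!length(spikeTimes)) stop("SNR is undefined without spikes")
  if (is.null(rate)) stop("rate is required for a plain vector")
  n <- length(x)
  g <- round(guard * rate)
  inSpike <- logical(n)
  for (t in spikeTimes) {
    i <- round(t * rate) + 1L
    inSpike[max(1L, i - g):min(n, i + g)] <- TRUE
  }
  if (all(inSpike)) stop("spike windows cover the whole trace; no noise left")
  rms(x[inSpike]) / rms(x[!inSpike])
}
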