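#' @import methods
NULL

#' Multichannel extracellular recording
#'
#' Container for a block of multichannel extracellular voltage data.  The
#' sample matrix is channels x time in microvolts; time is zero-based at the
#' recording start, sample index \code{s} (1-based) corresponds to time
#' \code{t0 + (s - 1) / rate} seconds.
#'
#' @slot samples numeric matrix, channels x samples, in microvolts.
#' @slot rate sampling rate in Hz.
#' @slot channelIds unique character labels, one per channel.
#' @slot regions per-channel anatomical region tag (e.g. "MO", "HIP", "VIS").
#' @slot t0 recording start time in seconds.
#'
#' @seealso [Recording()] for the user-facing constructor,
#'   [readRecording()] / [writeRecording()] for on-disk form.
#' @export
setClass("Recording",
  representation(
    samples = "matrix",
    rate = "numeric",
    channelIds = "character",
    regions = "character",
    t0 = "numeric"
  )
)

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1 || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  else if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "samples must contain no missing or non-finite values")
  if (nrow(object@samples) != length(object@channelIds))
    msg <- c(msg, "one channelId per sample-matrix row is required")
  if (anyDuplicated(object@channelIds))
    msg <- c(msg, "channelIds must be unique")
  if (length(object@regions) != length(object@channelIds))
    msg <- c(msg, "one region tag per channel is required")
  if (length(object@t0) != 1 || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param samples numeric matrix, channels x samples (microvolts).  A plain
#'   vector is treated as a single channel.
#' @param rate sampling rate in Hz.
#' @param channelIds channel labels; defaults to `"ch1" ... "chN"`.
#' @param regions per-channel region tags; defaults to `"unknown"`.
#' @param t0 recording start time in seconds (default 0).
#' @return A [Recording-class] object.
#' @examples
#' rec <- Recording(matrix(rnorm(2000), nrow = 2), rate = 1000)
#' nChannels(rec)
#' duration(rec)
#' @export
Recording <- function(samples, rate, channelIds = NULL, regions = NULL,
                      t0 = 0) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  storage.mode(samples) <- "double"
  if (is.null(channelIds)) channelIds <- paste0("ch", seq_len(nrow(samples)))
  if (is.null(regions)) regions <- rep("unknown", nrow(samples))
  new("Recording", samples = samples, rate = as.numeric(rate),
      channelIds = as.character(channelIds), regions = as.character(regions),
      t0 = as.numeric(t0))
}

#' Spike times on one channel
#'
#' @slot channelId channel the spikes were detected on.
#' @slot spikeTimes spike times in seconds, strictly increasing.
#' @export
setClass("SpikeTrain",
  representation(channelId = "character", spikeTimes = "numeric")
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@channelId) != 1)
    msg <- c(msg, "channelId must be a single label")
  st <- object@spikeTimes
  if (anyNA(st) || any(!is.finite(st)))
    msg <- c(msg, "spikeTimes must be finite")
  if (length(st) > 1 && any(diff(st) <= 0))
    msg <- c(msg, "spikeTimes must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname SpikeTrain-class
#' @param channelId channel label.
#' @param spikeTimes spike times in seconds, strictly increasing.
#' @export
SpikeTrain <- function(channelId, spikeTimes) {
  new("SpikeTrain", channelId = as.character(channelId),
      spikeTimes = as.numeric(spikeTimes))
}

#' Aligned spike waveform snippets
#'
#' Waveform windows cut around detected spikes, aligned so that the trough
#' of every snippet sits at (1-based) column `preSamples + 1`.
#'
#' @slot waveforms numeric matrix, n_spikes x n_samples, microvolts.
#' @slot preSamples samples before the trough.
#' @slot postSamples samples after the trough.
#' @slot rate sampling rate in Hz.
#' @slot spikeTimes trough times in seconds, one per row.
#' @export
setClass("SnippetArray",
  representation(
    waveforms = "matrix",
    preSamples = "integer",
    postSamples = "integer",
    rate = "numeric",
    spikeTimes = "numeric"
  )
)

setValidity("SnippetArray", function(object) {
  msg <- character(0)
  n <- object@preSamples + object@postSamples + 1L
  if (ncol(object@waveforms) != n)
    msg <- c(msg, "snippet length must equal preSamples + postSamples + 1")
  if (nrow(object@waveforms) != length(object@spikeTimes))
    msg <- c(msg, "one spikeTime per waveform row is required")
  if (object@preSamples < 0L || object@postSamples < 0L)
    msg <- c(msg, "window sizes must be non-negative")
  if (length(object@rate) != 1 || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(msg)) msg else TRUE
})

SnippetArray <- function(waveforms, preSamples, postSamples, rate,
                         spikeTimes) {
  storage.mode(waveforms) <- "double"
  new("SnippetArray", waveforms = waveforms,
      preSamples = as.integer(preSamples),
      postSamples = as.integer(postSamples),
      rate = as.numeric(rate), spikeTimes = as.numeric(spikeTimes))
}

#' Ground truth attached to a simulated recording
#'
#' Records everything the generator knows: the true spike times of every
#' unit, the unit-to-channel map, the generating unit and LFP parameter
#' sets, and the configured noise level, so that detection, sorting and
#' phase-locking estimates can be scored against truth.
#'
#' @slot spikeTimes named list, true spike times (s) per unit.
#' @slot unitChannels named character, channel of each unit.
#' @slot units list of the generating `unitSpec` objects.
#' @slot lfp the generating `lfpSpec`.
#' @slot noiseRms configured spike-band noise rms (microvolts).
#' @slot templates named list of the sampled waveform templates (microvolts).
#' @export
setClass("GroundTruth",
  representation(
    spikeTimes = "list",
    unitChannels = "character",
    units = "list",
    lfp = "ANY",
    noiseRms = "numeric",
    templates = "list"
  )
)

#' @describeIn Recording-class number of channels
#' @param object,x a `Recording`.
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))
#' @export
setMethod("nChannels", "Recording", function(object) nrow(object@samples))

#' @describeIn Recording-class number of samples per channel
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))
#' @export
setMethod("nSamples", "Recording", function(object) ncol(object@samples))

#' @describeIn Recording-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @export
setMethod("samplingRate", "Recording", function(object) object@rate)
#' @export
setMethod("samplingRate", "SnippetArray", function(object) object@rate)

#' @describeIn Recording-class duration in seconds (n_samples / rate)
#' @export
setGeneric("duration", function(object) standardGeneric("duration"))
#' @export
setMethod("duration", "Recording",
          function(object) ncol(object@samples) / object@rate)

#' @describeIn Recording-class channel labels
#' @export
setGeneric("channelIds", function(object) standardGeneric("channelIds"))
#' @export
setMethod("channelIds", "Recording", function(object) object@channelIds)

#' @describeIn Recording-class per-channel region tags
#' @export
setGeneric("regions", function(object) standardGeneric("regions"))
#' @export
setMethod("regions", "Recording", function(object) object@regions)

#' @describeIn Recording-class the channels x samples voltage matrix (uV)
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))
#' @export
setMethod("voltages", "Recording", function(object) object@samples)

#' Extract one channel's trace as a numeric vector
#' @param object a `Recording`.
#' @param channel channel label or index.
#' @return numeric vector of samples (microvolts).
#' @export
setGeneric("channelTrace",
           function(object, channel) standardGeneric("channelTrace"))
#' @export
setMethod("channelTrace", "Recording", function(object, channel) {
  if (is.character(channel)) {
    i <- match(channel, object@channelIds)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else i <- channel
  object@samples[i, ]
})

#' @describeIn SpikeTrain-class spike times in seconds
#' @param object a `SpikeTrain` or `SnippetArray`.
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))
#' @export
setMethod("spikeTimes", "SpikeTrain", function(object) object@spikeTimes)
#' @export
setMethod("spikeTimes", "SnippetArray", function(object) object@spikeTimes)

#' @describeIn SnippetArray-class the n_spikes x n_samples waveform matrix
#' @param object a `SnippetArray`.
#' @export
setGeneric("waveforms", function(object) standardGeneric("waveforms"))
#' @export
setMethod("waveforms", "SnippetArray", function(object) object@waveforms)

#' @describeIn SnippetArray-class number of spikes
#' @export
setGeneric("nSpikes", function(object) standardGeneric("nSpikes"))
#' @export
setMethod("nSpikes", "SnippetArray", function(object) nrow(object@waveforms))
#' @export
setMethod("nSpikes", "SpikeTrain", function(object) length(object@spikeTimes))

#' @describeIn SnippetArray-class samples before the aligned trough
#' @export
setGeneric("preSamples", function(object) standardGeneric("preSamples"))
#' @export
setMethod("preSamples", "SnippetArray", function(object) object@preSamples)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              ncol(object@samples) / object@rate))
  cat("  channels:", paste(utils::head(object@channelIds, 6), collapse = ", "),
      if (length(object@channelIds) > 6) "..." else "", "\n")
  cat("  regions: ", paste(unique(object@regions), collapse = ", "), "\n")
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain on %s: %d spike(s)\n", object@channelId,
              length(object@spikeTimes)))
})

setMethod("show", "SnippetArray", function(object) {
  cat(sprintf(
    "SnippetArray: %d spike(s) x %d samples (pre %d, post %d) @ %g Hz\n",
    nrow(object@waveforms), ncol(object@waveforms), object@preSamples,
    object@postSamples, object@rate))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d unit(s), spike-band noise rms %g uV\n",
              length(object@spikeTimes), object@noiseRms))
  for (u in names(object@spikeTimes))
    cat(sprintf("  %s on %s: %d spikes\n", u, object@unitChannels[[u]],
                length(object@spikeTimes[[u]])))
})
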