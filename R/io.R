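# On-disk formats: flat binary sample payload (<stem>.bin) with a JSON
# header sidecar (<stem>.json), and UTF-8 tab-separated tables with one
# header line for events and spikes.

headerPath <- function(path) paste0(path, ".json")
payloadPath <- function(path) paste0(path, ".bin")

#' Write a recording to disk
#'
#' Writes a flat binary payload (`<path>.bin`) plus a JSON header sidecar
#' (`<path>.json`).  The default encoding is little-endian float32 in
#' channel-major order (each channel's samples contiguous); int16 with a
#' microvolt scale factor is available via `dtype = "int16"`.
#'
#' @param recording a [Recording-class].
#' @param path file stem (no extension); `.bin` and `.json` are appended.
#' @param dtype `"float32"` (default), `"float64"` or `"int16"`.
#' @param scaleUv microvolts per integer unit, used only for `"int16"`.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(recording, path, dtype = c("float32", "float64",
                                                      "int16"),
                           scaleUv = 1) {
  stopifnot(is(recording, "Recording"))
  dtype <- match.arg(dtype)
  validObject(recording)
  header <- list(
    rate_hz = recording@rate,
    n_channels = nrow(recording@samples),
    n_samples = ncol(recording@samples),
    dtype = dtype,
    order = "channel-major",
    scale_uV = scaleUv,
    channel_ids = as.list(recording@channelIds),
    regions = as.list(recording@regions),
    t0_s = recording@t0
  )
  jsonlite::write_json(header, headerPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  # channel-major: rows of the matrix written one after another
  flat <- as.numeric(t(recording@samples))
  con <- file(payloadPath(path), "wb")
  on.exit(close(con))
  if (dtype == "float32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else if (dtype == "float64") {
    writeBin(flat, con, size = 8, endian = "little")
  } else {
    ints <- as.integer(round(flat / scaleUv))
    if (any(abs(ints) > .Machine$integer.max) ||
        any(ints > 32767L | ints < -32768L))
      stop("int16 overflow: increase scaleUv")
    writeBin(ints, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from disk
#'
#' Inverse of [writeRecording()].  For float32 payloads the pair
#' round-trips bit-exactly.
#'
#' @param path file stem as given to [writeRecording()].
#' @return A [Recording-class].
#' @export
readRecording <- function(path) {
  hp <- headerPath(path)
  if (!file.exists(hp)) stop("recording header not found: ", hp)
  header <- tryCatch(jsonlite::read_json(hp),
                     error = function(e) stop("corrupt recording header: ",
                                              conditionMessage(e)))
  for (key in c("rate_hz", "n_channels", "n_samples", "dtype", "order",
                "scale_uV", "channel_ids", "regions", "t0_s"))
    if (is.null(header[[key]]))
      stop("recording header is missing key: ", key)
  pp <- payloadPath(path)
  if (!file.exists(pp)) stop("recording payload not found: ", pp)
  nch <- as.integer(header$n_channels)
  ns <- as.integer(header$n_samples)
  n <- nch * ns
  con <- file(pp, "rb")
  on.exit(close(con))
  bytes <- switch(header$dtype, float32 = 4L, float64 = 8L, int16 = 2L,
                  stop("unknown dtype: ", header$dtype))
  avail <- file.size(pp) / bytes
  if (avail != n)
    stop(sprintf(
      "payload size mismatch: header declares %d channels x %d samples but payload holds %g values",
      nch, ns, avail))
  flat <- if (header$dtype == "int16") {
    as.numeric(readBin(con, integer(), n = n, size = 2, endian = "little",
                       signed = TRUE)) * header$scale_uV
  } else {
    readBin(con, numeric(), n = n, size = bytes, endian = "little")
  }
  samples <- if (identical(header$order, "interleaved")) {
    matrix(flat, nrow = nch, ncol = ns)          # sample-major on disk
  } else {
    matrix(flat, nrow = nch, ncol = ns, byrow = TRUE)
  }
  Recording(samples, rate = header$rate_hz,
            channelIds = unlist(header$channel_ids),
            regions = unlist(header$regions), t0 = header$t0_s)
}

#' Validate / construct a behavioral event table
#'
#' An event table is a data.frame with columns `label`, `t_start`, `t_end`
#' (seconds).  Epochs are half-open `[t_start, t_end)`; epochs sharing a
#' label must not overlap.
#'
#' @param label epoch labels (character).
#' @param t_start,t_end epoch boundaries in seconds.
#' @return validated data.frame.
#' @export
eventTable <- function(label, t_start, t_end) {
  df <- data.frame(label = as.character(label),
                   t_start = as.numeric(t_start),
                   t_end = as.numeric(t_end),
                   stringsAsFactors = FALSE)
  validateEvents(df)
}

validateEvents <- function(df) {
  need <- c("label", "t_start", "t_end")
  if (!all(need %in% names(df)))
    stop("event table needs columns: ", paste(need, collapse = ", "))
  bad <- which(df$t_start >= df$t_end)
  if (length(bad))
    stop("t_start >= t_end at event row ", bad[1])
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, , drop = FALSE]
    if (nrow(sub) > 1) {
      o <- order(sub$t_start)
      s <- sub$t_start[o]; e <- sub$t_end[o]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping epochs with label '", lab, "'")
    }
  }
  df
}

#' Read a behavioral event table (TSV)
#' @param path TSV file with header `label  t_start  t_end`.
#' @return validated event data.frame.
#' @export
readEvents <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric"))
  if (nrow(df) == 0)
    return(data.frame(label = character(0), t_start = numeric(0),
                      t_end = numeric(0), stringsAsFactors = FALSE))
  validateEvents(df)
}

#' Write a behavioral event table (TSV)
#' @param events validated event data.frame.
#' @param path output path.
#' @export
writeEvents <- function(events, path) {
  validateEvents(events)
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write detected spikes with cluster labels (TSV)
#'
#' One row per spike: `channel`, `spike_time_s`, `cluster`; rows sorted by
#' time within channel.  Every spike carries exactly one label.
#'
#' @param spikeTrains a [SpikeTrain-class] or list of them.
#' @param clusterLabels integer labels, one per spike, in the concatenated
#'   order of `spikeTrains`.
#' @param path output path.
#' @export
writeSpikeTable <- function(spikeTrains, clusterLabels, path) {
  if (is(spikeTrains, "SpikeTrain")) spikeTrains <- list(spikeTrains)
  nTotal <- sum(vapply(spikeTrains, function(s) length(s@spikeTimes), 0L))
  if (length(clusterLabels) != nTotal)
    stop(sprintf("label/spike length mismatch: %d labels for %d spikes",
                 length(clusterLabels), nTotal))
  rows <- list(); off <- 0L
  for (tr in spikeTrains) {
    n <- length(tr@spikeTimes)
    if (n > 0)
      rows[[length(rows) + 1]] <- data.frame(
        channel = tr@channelId,
        spike_time_s = tr@spikeTimes,
        cluster = clusterLabels[off + seq_len(n)],
        stringsAsFactors = FALSE)
    off <- off + n
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(channel = character(0), spike_time_s = numeric(0),
               cluster = integer(0))
  out <- out[order(out$channel, out$spike_time_s), , drop = FALSE]
  # full precision so a round-trip reproduces times exactly as printed
  out$spike_time_s <- sprintf("%.9f", out$spike_time_s)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spike table written by [writeSpikeTable()]
#' @param path TSV path.
#' @return data.frame with columns `channel`, `spike_time_s`, `cluster`.
#' @export
readSpikeTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "numeric", "integer"))
}
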