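# Behavioral epoch statistics and chronic-session tracking.

#' Firing statistics per behavioral epoch
#'
#' Spike counts and rates per epoch label.  Epochs are half-open
#' `[t_start, t_end)`, so a spike exactly at an epoch's end belongs to the
#' following epoch; spikes outside all epochs are reported under
#' `"unassigned"`.
#'
#' @param spikeTimes numeric vector of one unit's spike times (s), or a
#'   named list of such vectors for several units.
#' @param events validated event data.frame.
#' @return data.frame with columns `unit`, `label`, `count`, `duration_s`,
#'   `rate_hz` (`rate = count / duration`; the unassigned row has `NA`
#'   duration and rate).
#' @export
epochStats <- function(spikeTimes, events) {
  if (!is.list(spikeTimes)) spikeTimes <- list(unit1 = spikeTimes)
  if (is.null(names(spikeTimes)))
    names(spikeTimes) <- paste0("unit", seq_along(spikeTimes))
  validateEvents(events)
  labs <- unique(events$label)
  rows <- lapply(names(spikeTimes), function(u) {
    st <- spikeTimes[[u]]
    assigned <- rep(FALSE, length(st))
    out <- lapply(labs, function(lab) {
      sub <- events[events$label == lab, , drop = FALSE]
      cnt <- 0L
      for (i in seq_len(nrow(sub))) {
        inE <- st >= sub$t_start[i] & st < sub$t_end[i]
        cnt <- cnt + sum(inE)
        assigned[inE] <<- TRUE
      }
      dur <- sum(sub$t_end - sub$t_start)
      data.frame(unit = u, label = lab, count = cnt, duration_s = dur,
                 rate_hz = cnt / dur, stringsAsFactors = FALSE)
    })
    out[[length(out) + 1]] <- data.frame(
      unit = u, label = "unassigned", count = sum(!assigned),
      duration_s = NA_real_, rate_hz = NA_real_, stringsAsFactors = FALSE)
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

#' Left/right turn bias of a unit
#'
#' Per trial (left and right epochs paired by row order), the left spike
#' fraction `n_L / (n_L + n_R)`; trials with no spikes in either epoch are
#' excluded from the mean and reported.
#'
#' @param spikeTimes one unit's spike times (s).
#' @param leftEpochs,rightEpochs event data.frames with one row per trial,
#'   equal row counts.
#' @return list with `fractions` (per included trial), `mean`, `sd`,
#'   `nTrials` (included) and `nEmpty` (excluded).
#' @export
turnBias <- function(spikeTimes, leftEpochs, rightEpochs) {
  if (nrow(leftEpochs) != nrow(rightEpochs))
    stop("left and right trials must be paired (equal row counts)")
  countIn <- function(ep, i)
    sum(spikeTimes >= ep$t_start[i] & spikeTimes < ep$t_end[i])
  fr <- numeric(0)
  nEmpty <- 0L
  for (i in seq_len(nrow(leftEpochs))) {
    nL <- countIn(leftEpochs, i)
    nR <- countIn(rightEpochs, i)
    if (nL + nR == 0) {
      nEmpty <- nEmpty + 1L
      next
    }
    fr <- c(fr, nL / (nL + nR))
  }
  if (!length(fr))
    stop("turn bias is undefined: no spikes in any trial")
  list(fractions = fr, mean = mean(fr),
       sd = if (length(fr) > 1) stats::sd(fr) else NA_real_,
       nTrials = length(fr), nEmpty = nEmpty)
}

#' Linear LFP trend within an epoch
#'
#' Ordinary least-squares line through the epoch's samples; the slope sign
#' summarizes rising or falling field potential during the epoch.
#'
#' @param x LFP trace (microvolts).
#' @param rate sampling rate, Hz.
#' @param tStart,tEnd epoch boundaries, s.
#' @param t0 trace start time, s.
#' @return list with `slope` (microvolts/s), `intercept` (microvolts at
#'   `tStart`) and `fitted` values over the epoch.
#' @export
lfpTrendSlope <- function(x, rate, tStart, tEnd, t0 = 0) {
  i0 <- max(1L, round((tStart - t0) * rate) + 1L)
  i1 <- min(length(x), round((tEnd - t0) * rate) + 1L)
  if (i1 - i0 < 1) stop("epoch spans fewer than 2 samples")
  t <- (seq(i0, i1) - 1) / rate + t0 - tStart
  fit <- stats::lm.fit(cbind(1, t), x[i0:i1])
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       fitted = fit$fitted.values)
}

#' Single-unit recording yield
#'
#' Percentage of implanted channels carrying sortable single units,
#' rounded to the nearest integer (half away from zero), the convention
#' under which 5 of 12 channels prints as 42%.
#'
#' @param nSortable channels with sortable units.
#' @param nChannels implanted channels.
#' @return integer percent.
#' @export
recordingYield <- function(nSortable, nChannels) {
  if (nChannels < 1) stop("nChannels must be >= 1")
  if (nSortable < 0 || nSortable > nChannels)
    stop("nSortable must lie in [0, nChannels]")
  as.integer(floor(100 * nSortable / nChannels + 0.5))
}

#' Track units across chronic sessions
#'
#' Per session: mean spike amplitude, recording yield, and waveform
#' stability.  The amplitude is the peak-to-peak of the mean waveform over
#' all of the unit's spikes in the session (averaging first suppresses the
#' noise-range bias that inflates per-spike peak-to-peak at low
#' amplitudes); the dispersion reported alongside comes from `nSample`
#' randomly drawn single-spike amplitudes.  Stability is the Pearson
#' correlation of each session's peak-normalized mean waveform with the
#' first session that has spikes.
#'
#' @param sessions list with one element per session, each a list with
#'   `week`, `snippets` (a [SnippetArray-class] or `NULL`), `nSortable`,
#'   `nChannels`.
#' @param nSample spikes drawn for the amplitude dispersion (default 10).
#' @param seed RNG seed for the dispersion subsample.
#' @return data.frame with columns `week`, `n_spikes`, `mean_amp_uv`,
#'   `amp_sd_uv`, `yield_pct`, `similarity`; the peak-normalized mean
#'   waveforms are attached as attribute `"waveforms"`.
#' @export
trackSessions <- function(sessions, nSample = 10, seed = 1) {
  if (!length(sessions)) stop("at least one session is required")
  normWf <- list()
  rows <- vector("list", length(sessions))
  withSeed(seed, {
    for (s in seq_along(sessions)) {
      ses <- sessions[[s]]
      yield <- recordingYield(ses$nSortable, ses$nChannels)
      snip <- ses$snippets
      if (is.null(snip) || nSpikes(snip) == 0) {
        rows[[s]] <- data.frame(week = ses$week, n_spikes = 0L,
                                mean_amp_uv = NA_real_, amp_sd_uv = NA_real_,
                                yield_pct = yield, similarity = NA_real_)
        normWf[s] <- list(NULL)
        next
      }
      wf <- snip@waveforms
      meanWf <- colMeans(wf)
      # local baseline: remove the line through the window edges so slow
      # LFP leakage does not bias the peak-to-peak of small waveforms
      m <- ncol(wf)
      kEdge <- max(2L, min(5L, m %/% 8))
      iL <- mean(seq_len(kEdge)); iR <- mean(m - kEdge + seq_len(kEdge))
      yL <- mean(meanWf[seq_len(kEdge)])
      yR <- mean(meanWf[m - kEdge + seq_len(kEdge)])
      slope <- (yR - yL) / (iR - iL)
      meanWf <- meanWf - (yL + slope * (seq_len(m) - iL))
      # extrema on a 3-sample moving average: suppresses sample-level noise
      # in the peak-to-peak readout; distortion is negligible for troughs
      # wider than ~3 samples (0.12 ms at 24.4 kHz)
      sm <- stats::filter(meanWf, rep(1 / 3, 3), sides = 2)
      sm <- sm[!is.na(sm)]
      amp <- max(sm) - min(sm)
      pick <- sample.int(nrow(wf), min(nSample, nrow(wf)))
      ampSd <- stats::sd(apply(wf[pick, , drop = FALSE], 1, max) -
                         apply(wf[pick, , drop = FALSE], 1, min))
      normWf[[s]] <- meanWf / max(abs(meanWf))
      rows[[s]] <- data.frame(week = ses$week, n_spikes = nrow(wf),
                              mean_amp_uv = amp, amp_sd_uv = ampSd,
                              yield_pct = yield, similarity = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  ref <- Find(Negate(is.null), normWf)
  if (!is.null(ref)) {
    for (s in seq_along(sessions)) {
      if (is.null(normWf[[s]])) next
      out$similarity[s] <- stats::cor(ref, normWf[[s]])
    }
  }
  attr(out, "waveforms") <- normWf
  out
}
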