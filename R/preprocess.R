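## Preprocessing: line-noise notch, bipolar re-referencing, epoching and
## artifact / incorrect-trial exclusion.

#' Notch-filter line noise
#'
#' Zero-phase Butterworth band-stop of \code{width} Hz centred at
#' \code{base} Hz and its harmonics below 0.9 x Nyquist (at 512 Hz: 50,
#' 100, 150, 200 Hz).  The prototype order 2 gives a 4th-order band-stop
#' transfer function; forward-backward application doubles the attenuation
#' and cancels phase shift.
#'
#' @param rec a \linkS4class{ContinuousRecording} with rate >= 200 Hz.
#' @param base line frequency (Hz); @param width stop-band width (Hz).
#' @return The filtered recording.
#' @export
notchFilter <- function(rec, base = 50, width = 1) {
  stopifnot(is(rec, "ContinuousRecording"))
  rate <- samplingRate(rec)
  if (rate < 200) stop("notchFilter requires rate >= 200 Hz")
  x <- samples(rec)
  k <- 1
  while (k * base + width / 2 < 0.9 * rate / 2) {
    x <- butterFiltfilt(x, rate, c(k * base - width / 2, k * base + width / 2),
                        type = "stop", order = 2)
    k <- k + 1
  }
  initialize(rec, samples = x)
}

#' Bipolar re-referencing
#'
#' Derives one channel per adjacent same-shaft contact pair (next contact
#' minus current), excluding pairs that involve a bad or seizure-onset-zone
#' contact.  This annihilates any signal common to both contacts (volume
#' conduction, shared reference).  The derived channel is labelled with
#' the deeper contact's region (the lower contact index; override in the
#' channel table if the functional response argues otherwise).  Shafts
#' left with fewer than two usable contacts are dropped with a warning.
#'
#' @param rec a \linkS4class{ContinuousRecording} of contacts.
#' @return A \linkS4class{ContinuousRecording} of bipolar channels.
#' @export
bipolarReference <- function(rec) {
  stopifnot(is(rec, "ContinuousRecording"))
  ct <- channelTable(rec)
  x <- samples(rec)
  rows <- list(); sigs <- list()
  for (sh in unique(ct$shaft)) {
    onShaft <- which(ct$shaft == sh)
    onShaft <- onShaft[order(ct$contact_index[onShaft])]
    usable <- onShaft[!ct$bad[onShaft] & !ct$soz[onShaft]]
    if (length(usable) < 2) {
      warning("shaft ", sh, " has fewer than 2 usable contacts; dropped")
      next
    }
    ci <- ct$contact_index[usable]
    adjacent <- which(diff(ci) == 1)
    if (!length(adjacent)) {
      warning("shaft ", sh, " has no adjacent usable contact pair; dropped")
      next
    }
    for (a in adjacent) {
      i <- usable[a]; j <- usable[a + 1]
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0(ct$name[i], "-", ct$name[j]),
        shaft = sh, contact_index = ct$contact_index[i],
        region = ct$region[i], hemisphere = ct$hemisphere[i],
        bad = FALSE, soz = FALSE)
      sigs[[length(sigs) + 1L]] <- x[j, ] - x[i, ]
    }
  }
  if (!length(rows)) stop("no bipolar channels could be derived")
  new("ContinuousRecording", samples = do.call(rbind, sigs),
      rate = samplingRate(rec),
      channels = do.call(rbind, c(rows, make.row.names = FALSE)),
      sessionId = sessionId(rec))
}

## Per-segment sample counts of the assembled epoch.  The delay segment is
## taken from 0.2 s after delay-phase onset for exactly 3.8 s (the
## jittered 0.0-0.2 s head is dropped; any residual jitter tail before
## recall is discarded), split into 1.9 + 1.9 s halves.
.segmentCounts <- function(rate, baselineLength) {
  c(baseline = floor(baselineLength * rate),
    encoding = floor(2.0 * rate),
    delay1 = floor(1.9 * rate),
    delay2 = floor(3.8 * rate) - floor(1.9 * rate),
    recall = floor(2.0 * rate))
}

.periodTable <- function(baselineLength) {
  data.frame(period = PERIODS,
             start = c(-baselineLength, 0, 2.0, 3.9, 5.8),
             end = c(0, 2.0, 3.9, 5.8, 7.8))
}

#' Column indices of one task period within an EpochSet
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param period one of baseline, encoding, delay1, delay2, recall.
#' @return Integer vector of time indices into the epoch array.
#' @export
periodSamples <- function(epochs, period) {
  .periodIdx(epochs@rate, -epochs@window[1], period)
}

.periodIdx <- function(rate, baselineLength, period) {
  counts <- .segmentCounts(rate, baselineLength)
  period <- match.arg(period, PERIODS)
  k <- match(period, PERIODS)
  offset <- if (k == 1) 0L else sum(counts[seq_len(k - 1)])
  offset + seq_len(counts[k])
}

#' Cut fixed-layout epochs from a continuous recording
#'
#' Assembles per-trial epochs by concatenating the last
#' \code{baselineLength} s of fixation, the 2.0 s encoding phase, the
#' delay from 0.2 s to 4.0 s after delay onset (3.8 s, split into two
#' 1.9 s halves) and the 2.0 s action/recall phase.  Sample counts per
#' segment are fixed by \code{rate}, so every epoch has identical length
#' regardless of jitter.
#'
#' @param rec a \linkS4class{ContinuousRecording} (any rate; call after
#'   decimation for envelope-grid epochs).
#' @param events validated events data.frame.
#' @param baselineLength baseline seconds before encoding onset: 0.5 for
#'   the power analysis, 1.9 for the connectivity analysis.
#' @return An \linkS4class{EpochSet} with window
#'   \code{[-baselineLength, 7.8]} s.
#' @export
epochRecording <- function(rec, events, baselineLength = 0.5) {
  stopifnot(is(rec, "ContinuousRecording"))
  validateEvents(events)
  rate <- samplingRate(rec)
  x <- samples(rec)
  counts <- .segmentCounts(rate, baselineLength)
  nT <- nrow(events); nC <- nrow(x); nS <- sum(counts)
  data <- array(0, dim = c(nT, nC, nS))
  segStartRel <- c(-baselineLength, 0, 2.2, 2.2 + 1.9, NA)
  for (i in seq_len(nT)) {
    starts <- events$onset[i] + c(segStartRel[1:4],
                                  2.0 + events$delay_s[i])
    col <- 1L
    for (s in seq_along(counts)) {
      i0 <- round(starts[s] * rate) + 1L
      i1 <- i0 + counts[s] - 1L
      if (i0 < 1 || i1 > ncol(x))
        stop(sprintf("epoch for trial %d falls outside the recording", i))
      data[i, , col:(col + counts[s] - 1L)] <- x[, i0:i1]
      col <- col + counts[s]
    }
  }
  new("EpochSet", data = data, rate = rate,
      window = c(-baselineLength, 7.8),
      periods = .periodTable(baselineLength),
      condition = factor(events$condition, levels = CONDITIONS),
      channels = channelTable(rec),
      excluded = matrix(FALSE, nT, nC),
      reason = matrix("", nT, nC))
}

#' Flag epochs contaminated by interictal spikes
#'
#' A simple amplitude/derivative detector standing in for a full clinical
#' spike detector: an epoch is flagged for a channel when the absolute
#' z-scored amplitude (per channel, statistics pooled over all epochs) or
#' the absolute z-scored first difference exceeds the thresholds anywhere
#' in the epoch.  Channels with (near-)zero variance are never flagged as
#' spikes (the z-score denominator is floored).
#'
#' @param epochs an \linkS4class{EpochSet} of raw-band data.
#' @param ampThreshold amplitude threshold in SDs (default 6).
#' @param derivThreshold first-difference threshold in SDs (default 8).
#' @return Logical trials x channels matrix.
#' @export
flagSpikeEpochs <- function(epochs, ampThreshold = 6, derivThreshold = 8) {
  stopifnot(is(epochs, "EpochSet"))
  d <- epochData(epochs)
  nT <- dim(d)[1]; nC <- dim(d)[2]
  flag <- matrix(FALSE, nT, nC)
  ## first differences across segment-assembly seams span non-contiguous
  ## source samples (the dropped delay head / jitter tail) and are not
  ## evidence of artifacts
  counts <- .segmentCounts(epochs@rate, -epochs@window[1])
  seams <- cumsum(counts)[-length(counts)]
  dvKeep <- setdiff(seq_len(dim(d)[3] - 1L), seams)
  for (ch in seq_len(nC)) {
    m <- matrix(d[, ch, ], nrow = nT)
    ## robust (median/MAD) scale so the artifacts themselves do not
    ## inflate the normalisation they are tested against
    sdv <- stats::mad(m)
    if (!is.finite(sdv) || sdv < 1e-9) next  # flat channel: bad, not spikes
    dv <- (m[, -1, drop = FALSE] -
             m[, -ncol(m), drop = FALSE])[, dvKeep, drop = FALSE]
    sdd <- max(stats::mad(dv), 1e-12)
    zAmp <- abs(m - stats::median(m)) / sdv
    zDer <- abs(dv) / sdd
    flag[, ch] <- apply(zAmp, 1, max) > ampThreshold |
      apply(zDer, 1, max) > derivThreshold
  }
  flag
}

#' Exclude trials with incorrect behavioral responses
#'
#' Trial-level (all-channel) exclusion of trials with an incorrect
#' joystick position response, or -- in the "different" condition -- an
#' incorrect identity button response.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param events events data.frame with correctness flags.
#' @return Logical trials x channels matrix.
#' @export
excludeIncorrect <- function(epochs, events) {
  stopifnot(is(epochs, "EpochSet"))
  bad <- !events$correct_position |
    (events$condition == "different" &
       !is.na(events$correct_identity) & !events$correct_identity)
  matrix(bad, nrow = nrow(events), ncol = dim(epochData(epochs))[2])
}

#' Record exclusions on an EpochSet
#'
#' Merges a trials x channels logical mask into the epoch set's exclusion
#' mask, recording \code{reason} (e.g. "spike", "incorrect_position",
#' "incorrect_identity") for newly excluded cells.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param mask logical trials x channels matrix.
#' @param reason single reason code.
#' @return The updated \linkS4class{EpochSet}.
#' @export
markExcluded <- function(epochs, mask, reason) {
  stopifnot(is(epochs, "EpochSet"), all(dim(mask) == dim(epochs@excluded)))
  newly <- mask & !epochs@excluded
  rs <- epochs@reason
  rs[newly] <- reason
  initialize(epochs, excluded = epochs@excluded | mask, reason = rs)
}
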