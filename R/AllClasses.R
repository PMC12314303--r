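#' @import methods
NULL

REGIONS <- c("IPL", "VTC", "HIP", "OTHER")
PERIODS <- c("baseline", "encoding", "delay1", "delay2", "recall")
CONDITIONS <- c("same", "different")

#' Envelope sampling rate (Hz)
#'
#' Band-power envelopes are decimated to this fixed rate, giving a time
#' resolution of 1/64 s = 15.625 ms.
#' @return A single number, 64.
#' @export
envelopeRate <- function() 64

#' Task-period boundaries of the standard epoch
#'
#' Epochs run from -0.5 s to 7.8 s relative to encoding onset and tile into
#' five periods: baseline (0.5 s, end of fixation), encoding (2.0 s),
#' delay1 (1.9 s), delay2 (1.9 s) and recall (2.0 s).  The 0.0-0.2 s
#' jittered head of the delay phase is dropped during epoch assembly so all
#' epochs share this fixed layout.
#'
#' @return A data.frame with columns \code{period}, \code{start}, \code{end}
#'   (seconds relative to encoding onset).
#' @export
periodBoundaries <- function() {
  data.frame(
    period = PERIODS,
    start  = c(-0.5, 0, 2.0, 3.9, 5.8),
    end    = c(0, 2.0, 3.9, 5.8, 7.8)
  )
}

validChannelTable <- function(object) {
  msg <- character()
  req <- c("name", "shaft", "contact_index", "region", "hemisphere",
           "bad", "soz")
  miss <- setdiff(req, names(object))
  if (length(miss))
    return(sprintf("missing channel-table column(s): %s",
                   paste(miss, collapse = ", ")))
  if (anyDuplicated(object$name))
    msg <- c(msg, "channel names must be unique")
  if (!all(object$region %in% REGIONS))
    msg <- c(msg, sprintf("region must be one of %s",
                          paste(REGIONS, collapse = "/")))
  if (!all(object$hemisphere %in% c("L", "R")))
    msg <- c(msg, "hemisphere must be L or R")
  for (s in unique(object$shaft)) {
    ci <- object$contact_index[object$shaft == s]
    if (any(ci < 1) || is.unsorted(ci, strictly = TRUE))
      msg <- c(msg, sprintf(
        "contact_index must be strictly increasing and >= 1 on shaft %s", s))
  }
  if (length(msg)) msg else TRUE
}

#' ContinuousRecording: multichannel continuous iEEG
#'
#' Holds a channels x time matrix of samples (microvolts), the sampling
#' rate, a channel table (one row per signal row) and a session identifier.
#'
#' @slot samples numeric matrix, channels x time, microvolts.
#' @slot rate sampling rate in Hz.
#' @slot channels data.frame with columns name, shaft, contact_index,
#'   region (IPL/VTC/HIP/OTHER), hemisphere (L/R), bad, soz.
#' @slot sessionId character scalar.
#' @export
setClass("ContinuousRecording",
  representation(samples = "matrix", rate = "numeric",
                 channels = "data.frame", sessionId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@rate) != 1 || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    if (anyNA(object@samples))
      msg <- c(msg, "samples must not contain NA/NaN")
    if (nrow(object@samples) != nrow(object@channels))
      msg <- c(msg, "channel table rows must match sample matrix rows")
    ct <- validChannelTable(object@channels)
    if (!isTRUE(ct)) msg <- c(msg, ct)
    if (length(msg)) msg else TRUE
  })

#' EpochSet: trials x channels x time epoched data
#'
#' Fixed-length epochs assembled around encoding onset with period
#' boundaries tiling the window exactly, a per-trial condition label and a
#' per-(trial, channel) exclusion mask with reason codes.
#'
#' @slot data numeric array, trials x channels x time.
#' @slot rate sampling rate of the epoch grid (Hz).
#' @slot window numeric length-2, epoch window in seconds relative to
#'   encoding onset.
#' @slot periods data.frame of period boundaries (period, start, end).
#' @slot condition factor of length trials with levels same/different.
#' @slot channels channel table for the channel dimension.
#' @slot excluded logical matrix trials x channels.
#' @slot reason character matrix trials x channels ("" where not excluded).
#' @export
setClass("EpochSet",
  representation(data = "array", rate = "numeric", window = "numeric",
                 periods = "data.frame", condition = "factor",
                 channels = "data.frame", excluded = "matrix",
                 reason = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3)
      return("data must be a trials x channels x time array")
    if (length(object@condition) != d[1])
      msg <- c(msg, "condition length must equal trial count")
    if (nrow(object@channels) != d[2])
      msg <- c(msg, "channel table rows must match channel dimension")
    if (!all(dim(object@excluded) == d[1:2]))
      msg <- c(msg, "exclusion mask must be trials x channels")
    pb <- object@periods
    if (nrow(pb)) {
      tol <- 1e-9
      if (abs(pb$start[1] - object@window[1]) > tol ||
          abs(pb$end[nrow(pb)] - object@window[2]) > tol ||
          (nrow(pb) > 1 && any(abs(pb$start[-1] - pb$end[-nrow(pb)]) > tol)))
        msg <- c(msg, "period boundaries must tile the epoch window exactly")
    }
    if (length(msg)) msg else TRUE
  })

#' ContinuousEnvelopes: whitened 1-Hz band amplitude envelopes
#'
#' Continuous (un-epoched) filter-Hilbert amplitude envelopes on the 64 Hz
#' envelope grid, one per 1-Hz band and channel, expressed as percent of
#' the per-band session mean (so each band's session mean is 100).
#'
#' @slot values numeric array, bands x channels x time (percent units).
#' @slot bands integer vector of band lower edges; band k covers [k, k+1) Hz.
#' @slot rate envelope sampling rate (64 Hz).
#' @slot channels channel table.
#' @slot sessionId character scalar.
#' @export
setClass("ContinuousEnvelopes",
  representation(values = "array", bands = "integer", rate = "numeric",
                 channels = "data.frame", sessionId = "character"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be bands x channels x time")
    if (d[1] != length(object@bands))
      return("band dimension must match bands vector")
    if (d[2] != nrow(object@channels))
      return("channel dimension must match channel table")
    TRUE
  })

#' EnvelopeSet: epoched band-aggregated power envelopes
#'
#' Trials x channels x time band power at 64 Hz in percent-of-session-mean
#' units, optionally baseline-corrected (per-trial baseline mean
#' subtracted).
#'
#' @slot values numeric array, trials x channels x time.
#' @slot band character band name ("theta" or "alpha").
#' @slot bandRange numeric length-2, band limits in Hz.
#' @slot rate 64 Hz.
#' @slot window epoch window (seconds).
#' @slot periods period boundary table.
#' @slot condition per-trial condition factor.
#' @slot channels channel table.
#' @slot excluded trials x channels logical exclusion mask.
#' @slot baselined logical: has the baseline mean been subtracted?
#' @export
setClass("EnvelopeSet",
  representation(values = "array", band = "character", bandRange = "numeric",
                 rate = "numeric", window = "numeric", periods = "data.frame",
                 condition = "factor", channels = "data.frame",
                 excluded = "matrix", baselined = "logical"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3) return("values must be trials x channels x time")
    if (length(object@condition) != d[1])
      return("condition length must equal trial count")
    if (nrow(object@channels) != d[2])
      return("channel table rows must match channel dimension")
    if (!all(dim(object@excluded) == d[1:2]))
      return("exclusion mask must be trials x channels")
    TRUE
  })

#' TrialSpectra: per-trial multitaper Fourier coefficients
#'
#' Complex Fourier coefficients per trial, taper, channel and frequency for
#' one task-period window, used by the PLV stage.
#'
#' @slot coefficients complex array, trials x tapers x channels x
#'   frequencies.
#' @slot frequencies numeric vector (Hz).
#' @slot period character: which task-period window.
#' @slot windowLength numeric, analysis window length (s).
#' @slot condition per-trial condition factor.
#' @slot channels channel table.
#' @slot excluded trials x channels logical mask carried from the epochs.
#' @export
setClass("TrialSpectra",
  representation(coefficients = "array", frequencies = "numeric",
                 period = "character", windowLength = "numeric",
                 condition = "factor", channels = "data.frame",
                 excluded = "matrix"),
  validity = function(object) {
    d <- dim(object@coefficients)
    if (length(d) != 4)
      return("coefficients must be trials x tapers x channels x frequencies")
    if (d[4] != length(object@frequencies))
      return("frequency dimension must match frequencies vector")
    if (nrow(object@channels) != d[3])
      return("channel dimension must match channel table")
    TRUE
  })

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording '%s': %d channel(s), %.1f s at %g Hz\n",
              object@sessionId, nrow(object@samples),
              ncol(object@samples) / object@rate, object@rate))
  tb <- table(factor(object@channels$region, levels = REGIONS))
  cat("  regions:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "),
      "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "EpochSet: %d trial(s) x %d channel(s) x %d sample(s) at %g Hz\n",
    d[1], d[2], d[3], object@rate))
  cat(sprintf("  window [%g, %g] s; %d excluded (trial,channel) cell(s)\n",
              object@window[1], object@window[2], sum(object@excluded)))
})

setMethod("show", "ContinuousEnvelopes", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "ContinuousEnvelopes: %d band(s) x %d channel(s) x %d sample(s) at %g Hz\n",
    d[1], d[2], d[3], object@rate))
  cat(sprintf("  bands %d-%d Hz (1 Hz bins), percent-of-session-mean units\n",
              min(object@bands), max(object@bands) + 1L))
})

setMethod("show", "EnvelopeSet", function(object) {
  d <- dim(object@values)
  cat(sprintf(
    "EnvelopeSet (%s %g-%g Hz): %d trial(s) x %d channel(s) x %d sample(s)\n",
    object@band, object@bandRange[1], object@bandRange[2], d[1], d[2], d[3]))
  cat(sprintf("  baseline-corrected: %s\n", object@baselined))
})

setMethod("show", "TrialSpectra", function(object) {
  d <- dim(object@coefficients)
  cat(sprintf(
    "TrialSpectra (%s, %.2g s window): %d trial(s) x %d taper(s) x %d channel(s) x %d frequencies\n",
    object@period, object@windowLength, d[1], d[2], d[3], d[4]))
})
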