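## Whitened filter-Hilbert band power: 1 Hz-band envelopes at 64 Hz in
## percent-of-session-mean units, band aggregation, sliding-window
## Wilcoxon/FDR active-channel detection and task-period means.

BAND_BINS <- list(theta = 2:6, alpha = 8:12)  # band k covers [k, k+1) Hz
BAND_RANGES <- list(theta = c(2, 7), alpha = c(8, 13))

#' Whitened filter-Hilbert amplitude envelopes
#'
#' For each consecutive non-overlapping 1 Hz band (band k covering
#' [k, k+1) Hz): zero-phase 3rd-order Butterworth band-pass of the entire
#' continuous recording, analytic-signal magnitude (Hilbert envelope),
#' anti-aliased decimation to 64 Hz, then division by the envelope's mean
#' over the whole session and multiplication by 100.  The division
#' flattens the 1/f spectral decay (whitening): every band's session mean
#' is exactly 100 by construction.
#'
#' @param rec a \linkS4class{ContinuousRecording} (rate >= 256 Hz,
#'   continuous -- epoch afterwards, not before).
#' @param fLo,fHi analysed range; bands k = fLo .. fHi-1.  The study
#'   design computes 2-120 Hz but analyses theta/alpha only, so
#'   restricting to \code{fHi = 13} saves most of the cost.
#' @param order band-pass prototype order.
#' @return A \linkS4class{ContinuousEnvelopes} object.
#' @export
filterHilbertEnvelope <- function(rec, fLo = 2, fHi = 120, order = 3) {
  stopifnot(is(rec, "ContinuousRecording"))
  rate <- samplingRate(rec)
  if (rate < 256) stop("filterHilbertEnvelope requires rate >= 256 Hz")
  if (rate %% envelopeRate() != 0)
    stop("rate must be an integer multiple of the 64 Hz envelope rate")
  bands <- seq.int(fLo, fHi - 1L)
  keep <- bands + 1 < rate / 2
  if (!all(keep)) {
    warning("skipping band(s) above Nyquist: ",
            paste(bands[!keep], collapse = ", "))
    bands <- bands[keep]
  }
  x <- samples(rec)
  factor <- rate / envelopeRate()
  nOut <- length(seq(1, ncol(x), by = factor))
  out <- array(0, dim = c(length(bands), nrow(x), nOut))
  for (bi in seq_along(bands)) {
    k <- bands[bi]
    for (ch in seq_len(nrow(x))) {
      bp <- butterFiltfilt(x[ch, ], rate, c(k, k + 1), type = "pass",
                           order = order)
      env <- Mod(analyticSignal(bp))
      env64 <- decimateSignal(env, rate, factor)
      out[bi, ch, ] <- 100 * env64 / mean(env64)
    }
  }
  new("ContinuousEnvelopes", values = out, bands = as.integer(bands),
      rate = envelopeRate(), channels = channelTable(rec),
      sessionId = sessionId(rec))
}

#' Aggregate 1 Hz envelopes into a named band and epoch them
#'
#' Averages the 1 Hz envelopes across the band's bins (theta: bands 2-6,
#' i.e. 2-7 Hz; alpha: bands 8-12, i.e. 8-13 Hz), cuts fixed-layout
#' epochs on the 64 Hz grid (window [-0.5, 7.8] s) and, when
#' \code{baselineCorrect}, subtracts each trial's and channel's mean over
#' the [-0.5, 0) s baseline.
#'
#' @param envs a \linkS4class{ContinuousEnvelopes} object.
#' @param band "theta" or "alpha", or an integer vector of 1 Hz band
#'   lower edges to average.
#' @param events events data.frame.
#' @param baselineCorrect subtract the per-trial baseline mean?
#' @return An \linkS4class{EnvelopeSet}.
#' @export
aggregateBand <- function(envs, band, events, baselineCorrect = TRUE) {
  stopifnot(is(envs, "ContinuousEnvelopes"))
  if (is.character(band)) {
    bandName <- match.arg(band, names(BAND_BINS))
    bins <- BAND_BINS[[bandName]]
    rng <- BAND_RANGES[[bandName]]
  } else {
    bins <- as.integer(band)
    bandName <- sprintf("%d-%dHz", min(bins), max(bins) + 1L)
    rng <- c(min(bins), max(bins) + 1)
  }
  sel <- match(bins, envs@bands)
  if (anyNA(sel))
    stop("missing 1 Hz band(s): ", paste(bins[is.na(sel)], collapse = ", "))
  agg <- apply(envs@values[sel, , , drop = FALSE], c(2, 3), mean)
  rec64 <- new("ContinuousRecording", samples = agg, rate = envs@rate,
               channels = channelTable(envs), sessionId = envs@sessionId)
  ep <- epochRecording(rec64, events, baselineLength = 0.5)
  vals <- epochData(ep)
  if (baselineCorrect) {
    bIdx <- periodSamples(ep, "baseline")
    bMean <- apply(vals[, , bIdx, drop = FALSE], c(1, 2), mean)
    vals <- sweep(vals, c(1, 2), bMean)
  }
  new("EnvelopeSet", values = vals, band = bandName, bandRange = rng,
      rate = envs@rate, window = ep@window, periods = ep@periods,
      condition = conditionLabels(ep), channels = channelTable(ep),
      excluded = exclusionMask(ep), baselined = baselineCorrect)
}

## Wilcoxon signed-rank p-value of paired differences; all-zero
## differences carry no evidence and return p = 1.
.signedRankP <- function(d) {
  d <- d[is.finite(d)]
  if (length(d) < 2 || all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
}

#' Detect channels with significant band-power changes
#'
#' For one condition: at every post-stimulus envelope sample t in
#' [0, 7.8] s, a paired Wilcoxon signed-rank test across trials compares
#' the trial's baseline mean ([-0.5, 0) s) with the envelope at t.  As a
#' conservative smoothing step each sample's p-value is replaced by the
#' maximum p within a centred six-sample (93.75 ms) window, then
#' Benjamini-Hochberg FDR correction is applied jointly across all time
#' samples and channels.  A channel is "active" if any corrected sample is
#' significant at \code{q}.
#'
#' @param env an \linkS4class{EnvelopeSet}.
#' @param condition "same" or "different".
#' @param q FDR level (default 0.05).
#' @param windowSamples smoothing window length (default 6).
#' @param minTrials channels with fewer usable trials are skipped with a
#'   warning.
#' @return A list of class \code{ActiveChannelReport}: \code{report}
#'   (data.frame: channel, region, band, condition, active, min_p_adj,
#'   n_sig_samples), \code{sigMask} (channels x post-stimulus-time logical),
#'   \code{pAdj} (corrected p matrix), \code{times} (seconds).
#' @export
detectActiveChannels <- function(env, condition, q = 0.05,
                                 windowSamples = 6, minTrials = 10) {
  stopifnot(is(env, "EnvelopeSet"))
  condition <- match.arg(condition, CONDITIONS)
  vals <- envelopeValues(env)
  nC <- dim(vals)[2]
  bIdx <- .periodIdx(env@rate, -env@window[1], "baseline")
  postIdx <- setdiff(seq_len(dim(vals)[3]), bIdx)
  nT <- length(postIdx)
  pRaw <- matrix(NA_real_, nC, nT)
  condSel <- env@condition == condition
  for (ch in seq_len(nC)) {
    use <- which(condSel & !env@excluded[, ch])
    if (length(use) < minTrials) {
      warning(sprintf("channel %s: only %d usable trial(s); skipped",
                      env@channels$name[ch], length(use)))
      next
    }
    base <- rowMeans(vals[use, ch, bIdx, drop = FALSE][, 1, ])
    post <- matrix(vals[use, ch, postIdx], nrow = length(use))
    d <- post - base
    pRaw[ch, ] <- apply(d, 2, .signedRankP)
  }
  ## centred max-p window, truncated at the epoch edges
  before <- (windowSamples - 1) %/% 2
  after <- windowSamples - 1 - before
  pSmooth <- pRaw
  for (t in seq_len(nT)) {
    win <- max(1, t - before):min(nT, t + after)
    pSmooth[, t] <- apply(pRaw[, win, drop = FALSE], 1, max)
  }
  tested <- !is.na(pSmooth)
  pAdj <- pSmooth
  pAdj[tested] <- stats::p.adjust(pSmooth[tested], method = "BH")
  sig <- !is.na(pAdj) & pAdj < q
  report <- data.frame(
    channel = env@channels$name, region = env@channels$region,
    band = env@band, condition = condition,
    active = rowSums(sig) > 0,
    min_p_adj = suppressWarnings(apply(pAdj, 1, min, na.rm = TRUE)),
    n_sig_samples = rowSums(sig))
  report$min_p_adj[!is.finite(report$min_p_adj)] <- NA
  structure(list(report = report, sigMask = sig, pAdj = pAdj,
                 times = (postIdx - min(postIdx)) / env@rate),
            class = "ActiveChannelReport")
}

#' Task-period mean power for active channels
#'
#' Averages the (baseline-corrected) band envelope over each task period
#' per channel and condition, for the union of channels active in either
#' condition, yielding the table the mixed-effects stage consumes.
#'
#' @param env an \linkS4class{EnvelopeSet}.
#' @param reports list of \code{ActiveChannelReport}s (one per condition);
#'   NULL uses all channels.
#' @param patient patient identifier to attach.
#' @return data.frame: patient, channel, region, band, condition, period,
#'   mean_power, n_trials.
#' @export
averageTaskPeriods <- function(env, reports = NULL, patient = "P1") {
  stopifnot(is(env, "EnvelopeSet"))
  keep <- rep(TRUE, nrow(env@channels))
  if (!is.null(reports)) {
    if (inherits(reports, "ActiveChannelReport")) reports <- list(reports)
    act <- Reduce(`|`, lapply(reports, function(r) r$report$active))
    keep <- act
  }
  vals <- envelopeValues(env)
  empty <- data.frame(patient = character(), channel = character(),
                      region = character(), band = character(),
                      condition = character(), period = character(),
                      mean_power = numeric(), n_trials = integer())
  if (!any(keep)) return(empty)
  rows <- list()
  for (ch in which(keep)) for (cond in CONDITIONS) {
    use <- which(env@condition == cond & !env@excluded[, ch])
    for (p in PERIODS) {
      idx <- .periodIdx(env@rate, -env@window[1], p)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = patient, channel = env@channels$name[ch],
        region = env@channels$region[ch], band = env@band,
        condition = cond, period = p,
        mean_power = mean(vals[use, ch, idx]),
        n_trials = length(use))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
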