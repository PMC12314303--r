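## End-to-end orchestration: preprocessing, band power, PLV, GC, and the
## assembly of the period-mean tables the mixed-effects stage consumes.

#' Channel pairs between two regions (within hemisphere)
#'
#' @param channels channel table of bipolar channels.
#' @param regionPair length-2 character (e.g. c("IPL", "VTC")).
#' @return data.frame: i, j (channel indices), pair_id.
#' @export
regionChannelPairs <- function(channels, regionPair) {
  rows <- list()
  for (h in unique(channels$hemisphere)) {
    a <- which(channels$region == regionPair[1] & channels$hemisphere == h)
    b <- which(channels$region == regionPair[2] & channels$hemisphere == h)
    for (i in a) for (j in b)
      rows[[length(rows) + 1L]] <- data.frame(
        i = i, j = j,
        pair_id = paste(channels$name[i], channels$name[j], sep = "~"))
  }
  if (!length(rows)) return(data.frame(i = integer(), j = integer(),
                                       pair_id = character()))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Preprocess a contact-level recording
#'
#' Notch filter, bipolar re-referencing, signal-grid epoching (1.9 s
#' baseline), spike-epoch flagging and incorrect-trial exclusion.
#'
#' @param rec contact-level \linkS4class{ContinuousRecording}.
#' @param events events data.frame.
#' @return list: \code{recording} (bipolar, notch-filtered),
#'   \code{epochs} (signal-grid \linkS4class{EpochSet} with exclusions),
#'   \code{spikeMask}, \code{incorrectMask}.
#' @export
preprocessSession <- function(rec, events) {
  recN <- notchFilter(rec)
  recB <- bipolarReference(recN)
  ep <- epochRecording(recB, events, baselineLength = 1.9)
  spikes <- flagSpikeEpochs(ep)
  incorrect <- excludeIncorrect(ep, events)
  ep <- markExcluded(ep, spikes, "spike")
  ep <- markExcluded(ep, incorrect, "incorrect_position")
  list(recording = recB, epochs = ep, spikeMask = spikes,
       incorrectMask = incorrect)
}

#' Band-power stage
#'
#' Whitened filter-Hilbert envelopes for the analysed range, theta/alpha
#' aggregation, active-channel detection per condition and the
#' period-mean power table over the union of active channels.
#'
#' @param recB bipolar notch-filtered recording.
#' @param events events data.frame.
#' @param exclusions trials x channels logical mask from preprocessing.
#' @param bands band names to analyse.
#' @param patient patient label for the output table.
#' @return list per band: \code{envelopes} (EnvelopeSet), \code{reports}
#'   (per condition), plus combined \code{powerTable}.
#' @export
bandPowerStage <- function(recB, events, exclusions = NULL,
                           bands = c("theta", "alpha"), patient = "P1") {
  allBins <- sort(unique(unlist(BAND_BINS[bands])))
  envs <- filterHilbertEnvelope(recB, fLo = min(allBins),
                                fHi = max(allBins) + 1L)
  out <- list()
  tables <- list()
  for (b in bands) {
    es <- aggregateBand(envs, b, events)
    if (!is.null(exclusions))
      es@excluded <- es@excluded | exclusions
    reports <- lapply(CONDITIONS, function(cond)
      detectActiveChannels(es, cond))
    names(reports) <- CONDITIONS
    tables[[b]] <- averageTaskPeriods(es, reports, patient = patient)
    out[[b]] <- list(envelopes = es, reports = reports)
  }
  tables <- Filter(function(x) !is.null(x) && nrow(x) > 0, tables)
  out$powerTable <- if (length(tables))
    do.call(rbind, c(tables, make.row.names = FALSE)) else data.frame()
  out
}

#' PLV stage
#'
#' Multitaper spectra per task period, per-pair permutation/cluster tests
#' against baseline (all trials), Sig.P.Ratio band selection per region
#' pair, per-condition PLV spectra and period-averaged PLV tables over
#' the selected ranges.
#'
#' @param epochs signal-grid \linkS4class{EpochSet} (baseline 1.9 s).
#' @param regionPairs list of length-2 region vectors.
#' @param nPerm permutations per test.
#' @param seed RNG seed.
#' @param patient patient label.
#' @param alphaCluster cluster significance level.
#' @return list: \code{spectra}, \code{tests} (per pair x period),
#'   \code{pairTables} (per region pair: pairs, significant, masks),
#'   \code{sigRatio} (per region pair), \code{plvTable} (long),
#'   \code{periodMeans} (per region pair, over selected ranges).
#' @export
plvStage <- function(epochs, regionPairs = list(c("IPL", "VTC"),
                                                c("IPL", "HIP")),
                     nPerm = 200, seed = 1L, patient = "P1",
                     alphaCluster = 0.05) {
  specs <- lapply(PERIODS, function(p) multitaperSpectra(epochs, p))
  names(specs) <- PERIODS
  taskPeriods <- setdiff(PERIODS, "baseline")
  freqs <- specs$baseline@frequencies
  out <- list(spectra = specs, tests = list(), pairTables = list(),
              sigRatio = list(), periodMeans = list())
  plvRows <- list()
  for (rp in regionPairs) {
    key <- paste(rp, collapse = "-")
    pairs <- regionChannelPairs(epochs@channels, rp)
    if (!nrow(pairs)) next
    masks <- matrix(FALSE, nrow(pairs), length(freqs))
    sig <- logical(nrow(pairs))
    for (pi in seq_len(nrow(pairs))) {
      pairMask <- rep(FALSE, length(freqs))
      for (tp in taskPeriods) {
        tst <- permutationPLVTest(specs[[tp]], specs$baseline,
                                  pairs$i[pi], pairs$j[pi],
                                  nPerm = nPerm,
                                  alphaCluster = alphaCluster,
                                  seed = seed + pi)
        out$tests[[paste(key, pairs$pair_id[pi], tp, sep = "|")]] <- tst
        pairMask <- pairMask | tst$mask
      }
      masks[pi, ] <- pairMask
      sig[pi] <- any(pairMask)
      if (sig[pi]) {
        for (p in PERIODS) for (cond in CONDITIONS) {
          tr <- which(conditionLabels(epochs) == cond)
          plv <- computePLV(specs[[p]], pairs$i[pi], pairs$j[pi],
                            trials = tr)
          plvRows[[length(plvRows) + 1L]] <- data.frame(
            region_pair = key, patient = patient,
            pair_id = pairs$pair_id[pi], period = p, condition = cond,
            frequency = plv$frequency, plv = plv$plv)
        }
      }
    }
    out$pairTables[[key]] <- cbind(pairs, significant = sig)
    out$sigRatio[[key]] <- sigPairRatio(masks, frequencies = freqs)
  }
  out$plvTable <- if (length(plvRows))
    do.call(rbind, c(plvRows, make.row.names = FALSE)) else data.frame()
  for (key in names(out$sigRatio)) {
    rng <- out$sigRatio[[key]]$ranges
    tab <- out$plvTable[out$plvTable$region_pair == key, , drop = FALSE]
    if (nrow(rng) && nrow(tab))
      out$periodMeans[[key]] <- averagePLVPeriods(tab, rng)
  }
  out
}

#' Spectral GC stage
#'
#' Runs CSD, Wilson factorization and Geweke GC for the PLV-significant
#' pairs of each region pair, per task period (recall excluded) and
#' condition; selects net-GC peak bands from the grand average and
#' produces the period-mean net-GC tables.
#'
#' @param recB bipolar recording; @param events events data.frame.
#' @param pairTables \code{pairTables} element of \code{\link{plvStage}}
#'   (pairs with their significance flags).
#' @param exclusions trials x channels exclusion mask.
#' @param patient patient label.
#' @param minTrials minimum usable trials per CSD.
#' @return list: \code{gcTable} (long: region_pair, patient, pair_id,
#'   period, condition, frequency, gc_xy, gc_yx, net), \code{ranges}
#'   (per region pair), \code{periodMeans} (per region pair).
#' @export
grangerStage <- function(recB, events, pairTables, exclusions = NULL,
                         patient = "P1", minTrials = 10) {
  ep40 <- downsampleForGC(recB, events)
  if (!is.null(exclusions)) ep40@excluded <- ep40@excluded | exclusions
  gcPeriods <- c("baseline", "encoding", "delay1", "delay2")
  rows <- list()
  for (key in names(pairTables)) {
    pt <- pairTables[[key]]
    for (pi in which(pt$significant)) {
      for (p in gcPeriods) for (cond in CONDITIONS) {
        csd <- tryCatch(
          computeCSD(ep40, pt$i[pi], pt$j[pi], p, condition = cond,
                     minTrials = minTrials),
          error = function(e) NULL)
        if (is.null(csd)) next
        gc <- spectralGC(wilsonFactorize(csd))
        rows[[length(rows) + 1L]] <- data.frame(
          region_pair = key, patient = patient, pair_id = pt$pair_id[pi],
          period = p, condition = cond, frequency = gc$frequency,
          gc_xy = gc$gc_xy, gc_yx = gc$gc_yx, net = gc$net)
      }
    }
  }
  gcTable <- if (length(rows))
    do.call(rbind, c(rows, make.row.names = FALSE)) else data.frame()
  ranges <- list(); periodMeans <- list()
  for (key in unique(gcTable$region_pair)) {
    sub <- gcTable[gcTable$region_pair == key, ]
    agg <- stats::aggregate(net ~ frequency, data = sub, FUN = mean)
    rng <- selectPeakBand(agg$net, agg$frequency)
    ranges[[key]] <- rng
    if (nrow(rng))
      periodMeans[[key]] <- averageNetGCPeriods(sub, rng)
  }
  list(gcTable = gcTable, ranges = ranges, periodMeans = periodMeans)
}

#' Run the full pipeline on one session
#'
#' Preprocessing, band power, PLV and GC; mixed-effects fits are a
#' cohort-level operation (they need several patients), so this returns
#' the per-session tables ready for pooling.
#'
#' @param rec contact-level recording; @param events events table.
#' @param patient patient label; @param nPerm PLV permutations;
#' @param seed RNG seed.
#' @return list: \code{preprocessed}, \code{power}, \code{plv}, \code{gc}.
#' @export
runPipeline <- function(rec, events, patient = "P1", nPerm = 200,
                        seed = 1L) {
  pre <- preprocessSession(rec, events)
  excl <- exclusionMask(pre$epochs)
  power <- bandPowerStage(pre$recording, events, exclusions = excl,
                          patient = patient)
  plv <- plvStage(pre$epochs, nPerm = nPerm, seed = seed,
                  patient = patient)
  gc <- grangerStage(pre$recording, events, plv$pairTables,
                     exclusions = excl, patient = patient)
  list(preprocessed = pre, power = power, plv = plv, gc = gc)
}
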