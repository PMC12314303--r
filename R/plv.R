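## Phase-locking value: multitaper trial spectra, PLV, paired permutation
## test with cluster correction over frequency, Sig.P.Ratio binomial band
## selection and period-averaged PLV tables.

PLV_FREQS <- 2:20

## Analysis window (samples within the epoch) for one task period: the
## full 1.9/2.0 s segments, except recall which uses only its first 0.5 s
## (the pre-response part).
.plvWindow <- function(epochs, period) {
  idx <- periodSamples(epochs, period)
  if (period == "recall") idx <- idx[seq_len(floor(0.5 * epochs@rate))]
  idx
}

#' Multitaper trial spectra for one task period
#'
#' Per-trial, per-channel complex Fourier coefficients with two orthogonal
#' DPSS (Slepian) tapers (time-bandwidth 1.5), zero-padded to a 4 s FFT so
#' the grid contains the 2, 3, ..., 20 Hz bins exactly.  The recall window
#' is the 0.5 s before responses typically begin; all other windows are
#' the full task-period segments.  Frequencies below one cycle per window
#' are still computed but flagged unreliable.
#'
#' @param epochs a signal-grid \linkS4class{EpochSet} (use
#'   \code{epochRecording(..., baselineLength = 1.9)} so the baseline
#'   window is the last 1.9 s of fixation).
#' @param period task period name.
#' @param freqs frequency grid in Hz (integers; default 2-20).
#' @param taperFamily "dpss" (default) or "hann" (single Hann taper
#'   duplicated is never used; "sine" gives the 2-taper sine family).
#' @param nTapers number of tapers (default 2).
#' @return A \linkS4class{TrialSpectra}.
#' @export
multitaperSpectra <- function(epochs, period, freqs = PLV_FREQS,
                              taperFamily = c("dpss", "sine"),
                              nTapers = 2) {
  stopifnot(is(epochs, "EpochSet"))
  taperFamily <- match.arg(taperFamily)
  period <- match.arg(period, PERIODS)
  idx <- .plvWindow(epochs, period)
  rate <- epochs@rate
  nWin <- length(idx)
  winLen <- nWin / rate
  if (any(freqs < 1 / winLen))
    attr(freqs, "unreliable") <- freqs[freqs < 1 / winLen]
  nfft <- 4 * rate
  stopifnot(nWin <= nfft)
  freqIdx <- round(freqs * 4) + 1L       # grid spacing rate/nfft = 0.25 Hz
  tap <- switch(taperFamily,
                dpss = dpssTapers(nWin, 1.5, nTapers),
                sine = sineTapers(nWin, nTapers))
  d <- epochData(epochs)
  nT <- dim(d)[1]; nC <- dim(d)[2]
  co <- array(complex(real = 0), dim = c(nT, nTapers, nC, length(freqs)))
  pad <- matrix(0, nfft - nWin, nT)
  for (ch in seq_len(nC)) {
    seg <- t(matrix(d[, ch, idx], nrow = nT))   # time x trials
    for (k in seq_len(nTapers)) {
      X <- stats::mvfft(rbind(seg * tap[, k], pad))
      co[, k, ch, ] <- t(X[freqIdx, , drop = FALSE])
    }
  }
  new("TrialSpectra", coefficients = co, frequencies = as.numeric(freqs),
      period = period, windowLength = winLen,
      condition = conditionLabels(epochs), channels = channelTable(epochs),
      excluded = exclusionMask(epochs))
}

## Per-trial taper-summed unit cross-spectral terms for a channel pair:
## returns complex trials x freq matrix S (sum over tapers of
## X_i X_j* / |X_i||X_j|) and the matching count matrix.
.unitCross <- function(spec, i, j, trials) {
  Xi <- spec@coefficients[trials, , i, , drop = FALSE]
  Xj <- spec@coefficients[trials, , j, , drop = FALSE]
  num <- Xi * Conj(Xj)
  den <- Mod(Xi) * Mod(Xj)
  ok <- den > 0
  u <- array(complex(real = 0), dim = dim(num))
  u[ok] <- num[ok] / den[ok]
  list(S = apply(u, c(1, 4), sum), n = apply(ok, c(1, 4), sum))
}

#' Phase-locking value spectrum for a channel pair
#'
#' PLV(f) = |mean over trials and tapers of X_i X_j* / (|X_i| |X_j|)|.
#' Tapers are pooled as additional observations inside the mean
#' (coefficient-level pooling); trials excluded for either channel are
#' dropped, as are zero-magnitude coefficients at individual frequencies
#' (with the count adjusted).
#'
#' @param spec a \linkS4class{TrialSpectra}.
#' @param i,j channel indices or names.
#' @param trials optional subset of trial indices (on top of the exclusion
#'   mask).
#' @return data.frame: frequency, plv, n (number of pooled terms).
#' @export
computePLV <- function(spec, i, j, trials = NULL) {
  stopifnot(is(spec, "TrialSpectra"))
  if (is.character(i)) i <- match(i, spec@channels$name)
  if (is.character(j)) j <- match(j, spec@channels$name)
  use <- which(!spec@excluded[, i] & !spec@excluded[, j])
  if (!is.null(trials)) use <- intersect(use, trials)
  if (length(use) < 2) stop("need at least 2 common non-excluded trials")
  uc <- .unitCross(spec, i, j, use)
  n <- colSums(uc$n)
  plv <- ifelse(n > 0, Mod(colSums(uc$S)) / pmax(n, 1), NA)
  data.frame(frequency = spec@frequencies, plv = plv, n = n)
}

#' Permutation test of task-vs-baseline PLV with cluster correction
#'
#' The observed statistic is dPLV(f) = PLV_task(f) - PLV_baseline(f).
#' Under the null the two same-trial segments are exchangeable: each
#' permutation swaps the baseline/task segment labels within a random
#' subset of trials and recomputes dPLV.  Per frequency, the point-wise
#' threshold is the 95th percentile over the permutation dPLV values
#' together with the observed one (the identity permutation, keeping all
#' nPerm + 1 statistics exchangeable); contiguous
#' supra-threshold bins form clusters whose mass (sum of dPLV) is compared
#' against the permutation distribution of the maximal cluster mass
#' (one-sided, significant at \code{alphaCluster}).  Window-length
#' asymmetry (e.g. 0.5 s recall vs 1.9 s baseline) is inherited by the
#' null, preserving frequency-dependent bias.
#'
#' @param taskSpec,baseSpec \linkS4class{TrialSpectra} for the task period
#'   and baseline, same trials.
#' @param i,j channel indices or names.
#' @param nPerm number of permutations (>= 20; default 200).
#' @param alphaCluster cluster-level significance (default 0.05).
#' @param seed RNG seed recorded in the output.
#' @param trials optional subset of trial indices.
#' @return A list of class \code{PLVPermTest}: \code{frequency},
#'   \code{observed} (dPLV), \code{threshold} (per-frequency 95th
#'   percentile), \code{clusters} (data.frame lo, hi, mass, p),
#'   \code{mask} (logical per frequency: member of a surviving cluster),
#'   \code{significant} (any surviving cluster?), \code{nPerm},
#'   \code{seed}.
#' @export
permutationPLVTest <- function(taskSpec, baseSpec, i, j, nPerm = 200,
                               alphaCluster = 0.05, seed = 1L,
                               trials = NULL) {
  if (nPerm < 20) stop("nPerm must be >= 20 (95th percentile undefined)")
  if (is.character(i)) i <- match(i, taskSpec@channels$name)
  if (is.character(j)) j <- match(j, taskSpec@channels$name)
  excl <- taskSpec@excluded | baseSpec@excluded
  use <- which(!excl[, i] & !excl[, j])
  if (!is.null(trials)) use <- intersect(use, trials)
  if (length(use) < 2) stop("need at least 2 common non-excluded trials")
  ucT <- .unitCross(taskSpec, i, j, use)
  ucB <- .unitCross(baseSpec, i, j, use)
  nF <- length(taskSpec@frequencies)
  plvOf <- function(S, n) ifelse(n > 0, Mod(S) / pmax(n, 1), 0)
  obs <- plvOf(colSums(ucT$S), colSums(ucT$n)) -
    plvOf(colSums(ucB$S), colSums(ucB$n))
  set.seed(seed)
  N <- length(use)
  W <- matrix(stats::rbinom(nPerm * N, 1, 0.5), nPerm, N)
  permT <- W %*% ucB$S + (1 - W) %*% ucT$S     # nPerm x nF, complex
  permB <- W %*% ucT$S + (1 - W) %*% ucB$S
  cntT <- W %*% ucB$n + (1 - W) %*% ucT$n
  cntB <- W %*% ucT$n + (1 - W) %*% ucB$n
  permD <- plvOf(permT, cntT) - plvOf(permB, cntB)  # nPerm x nF
  ## the observed labeling enters the threshold as the identity
  ## permutation so all nPerm + 1 statistics are treated exchangeably
  thr <- apply(rbind(obs, permD), 2, stats::quantile, probs = 0.95,
               names = FALSE)
  clusterMasses <- function(dvec) {
    above <- dvec > thr
    if (!any(above)) return(data.frame(lo = integer(), hi = integer(),
                                       mass = numeric()))
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    kp <- which(r$values)
    data.frame(lo = starts[kp], hi = ends[kp],
               mass = vapply(kp, function(q)
                 sum(dvec[starts[q]:ends[q]]), 0))
  }
  nullMax <- vapply(seq_len(nPerm), function(p) {
    cm <- clusterMasses(permD[p, ])
    if (nrow(cm)) max(cm$mass) else 0
  }, 0)
  cl <- clusterMasses(obs)
  if (nrow(cl)) {
    cl$p <- vapply(cl$mass, function(m)
      (1 + sum(nullMax >= m)) / (nPerm + 1), 0)
  } else cl$p <- numeric()
  mask <- rep(FALSE, nF)
  for (q in which(cl$p < alphaCluster)) mask[cl$lo[q]:cl$hi[q]] <- TRUE
  structure(list(frequency = taskSpec@frequencies, observed = obs,
                 threshold = thr, clusters = cl, mask = mask,
                 significant = any(cl$p < alphaCluster),
                 nPerm = nPerm, seed = seed, nTrials = N,
                 pair = taskSpec@channels$name[c(i, j)],
                 period = taskSpec@period),
            class = "PLVPermTest")
}

#' Ratio of significant pairs per frequency bin, with binomial selection
#'
#' Sig.P.Ratio: the fraction of channel pairs between two regions whose
#' PLV is significant in each 1 Hz bin.  Each bin's count is tested
#' one-sided against the chance level p0 = the median ratio across bins
#' (exact binomial test), with Benjamini-Hochberg FDR correction across
#' bins; the selected frequency ranges are the maximal runs of
#' significant bins.  The chance level is floored at half a count
#' (0.5 / n pairs): with few pairs the median can be exactly zero, and a
#' binomial test against p0 = 0 would declare any single significant pair
#' "above chance".
#'
#' @param masks logical pairs x frequency-bins matrix (pair significant at
#'   that bin, pooled over task periods).
#' @param frequencies frequency-bin centres (Hz).
#' @param alphaFdr FDR level (default 0.05).
#' @param p0 chance level; defaults to the median ratio across bins.
#' @return A list of class \code{SigPairRatio}: \code{table} (data.frame
#'   frequency, n_significant, n_total, ratio, p, p_adj, selected),
#'   \code{median_ratio}, \code{ranges} (data.frame f_lo, f_hi in Hz).
#' @export
sigPairRatio <- function(masks, frequencies = PLV_FREQS, alphaFdr = 0.05,
                         p0 = NULL) {
  masks <- as.matrix(masks)
  nTotal <- nrow(masks)
  if (nTotal == 0) stop("no pairs analysed")
  nSig <- colSums(masks)
  ratio <- nSig / nTotal
  med <- stats::median(ratio)
  if (is.null(p0)) p0 <- max(med, 0.5 / nTotal)
  p <- vapply(nSig, function(k)
    stats::binom.test(k, nTotal, p = min(max(p0, 1e-12), 1 - 1e-12),
                      alternative = "greater")$p.value, 0)
  pAdj <- stats::p.adjust(p, method = "BH")
  sel <- pAdj < alphaFdr
  rng <- data.frame(f_lo = numeric(), f_hi = numeric())
  if (any(sel)) {
    r <- rle(sel)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    kp <- which(r$values)
    rng <- data.frame(f_lo = frequencies[starts[kp]],
                      f_hi = frequencies[ends[kp]])
  }
  structure(list(
    table = data.frame(frequency = frequencies, n_significant = nSig,
                       n_total = nTotal, ratio = ratio, p = p,
                       p_adj = pAdj, selected = sel),
    median_ratio = med, ranges = rng), class = "SigPairRatio")
}

#' Period-averaged PLV over selected frequency ranges
#'
#' For each selected frequency range, averages each pair's PLV over the
#' bins inside the range, per task period and condition, producing the
#' table the mixed-effects stage consumes.
#'
#' @param plvTable data.frame with columns patient, pair_id, period,
#'   condition, frequency, plv (long format, as produced by the pipeline).
#' @param ranges data.frame with columns f_lo, f_hi (Hz, inclusive).
#' @return data.frame: range, patient, pair_id, period, condition,
#'   mean_plv.
#' @export
averagePLVPeriods <- function(plvTable, ranges) {
  if (nrow(ranges) == 0) stop("no selected frequency ranges")
  out <- list()
  for (r in seq_len(nrow(ranges))) {
    sel <- plvTable$frequency >= ranges$f_lo[r] &
      plvTable$frequency <= ranges$f_hi[r]
    sub <- plvTable[sel, ]
    ag <- stats::aggregate(plv ~ patient + pair_id + period + condition,
                           data = sub, FUN = mean)
    names(ag)[names(ag) == "plv"] <- "mean_plv"
    ag$range <- sprintf("%g-%gHz", ranges$f_lo[r], ranges$f_hi[r])
    out[[r]] <- ag
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
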