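## Non-parametric spectral Granger causality: 40 Hz resampling, 2-taper
## cross-spectral density with 20 s zero-padding (0.05 Hz grid), Wilson
## spectral-matrix factorization S = H Sigma H*, Geweke's frequency-domain
## GC, net-GC peak-band selection and period-averaged tables.

#' Resample a recording and cut epochs for the GC stage
#'
#' Anti-aliased resampling of the continuous recording to 40 Hz followed
#' by fixed-layout epoching with a 1.9 s baseline; period boundaries are
#' preserved in seconds, so a 1.9 s segment holds exactly 76 samples.
#'
#' @param rec a \linkS4class{ContinuousRecording}.
#' @param events events data.frame.
#' @param newRate target rate (default 40 Hz).
#' @return An \linkS4class{EpochSet} at \code{newRate}.
#' @export
downsampleForGC <- function(rec, events, newRate = 40) {
  stopifnot(is(rec, "ContinuousRecording"))
  x <- samples(rec)
  y <- t(apply(x, 1, resampleSignal, rate = samplingRate(rec),
               newRate = newRate))
  rec40 <- new("ContinuousRecording", samples = y, rate = newRate,
               channels = channelTable(rec), sessionId = sessionId(rec))
  epochRecording(rec40, events, baselineLength = 1.9)
}

## 1.9 s GC analysis window for a period; encoding (2.0 s) is truncated
## to its first 1.9 s so all periods match, and recall is refused as too
## short for reliable spectral estimation.
.gcWindow <- function(epochs, period) {
  if (period == "recall")
    stop("recall period refused: too short for reliable spectral GC")
  idx <- periodSamples(epochs, period)
  n19 <- floor(1.9 * epochs@rate)
  idx[seq_len(n19)]
}

#' Cross-spectral density matrix for a channel pair
#'
#' Per-trial Fourier coefficients of the 1.9 s period window with two
#' orthogonal sine tapers (the 2-taper Hann-like family), zero-padded to
#' 20 s (0.05 Hz grid); the CSD is the average over trials and tapers of
#' the coefficient outer products, Hermitian by construction.
#'
#' @param epochs40 an \linkS4class{EpochSet} from
#'   \code{\link{downsampleForGC}}.
#' @param i,j channel indices or names.
#' @param period baseline, encoding, delay1 or delay2 (recall refused).
#' @param condition optional condition restriction.
#' @param minTrials minimum usable trials (default 10).
#' @param fMax highest retained frequency (Hz).
#' @return A list of class \code{CSDMatrix}: \code{S} (2 x 2 x F complex),
#'   \code{frequency}, \code{nTrials}, \code{nTapers}, \code{pair},
#'   \code{period}, \code{condition}.
#' @export
computeCSD <- function(epochs40, i, j, period, condition = NULL,
                       minTrials = 10, fMax = 20) {
  stopifnot(is(epochs40, "EpochSet"))
  if (is.character(i)) i <- match(i, epochs40@channels$name)
  if (is.character(j)) j <- match(j, epochs40@channels$name)
  idx <- .gcWindow(epochs40, period)
  rate <- epochs40@rate
  use <- which(!epochs40@excluded[, i] & !epochs40@excluded[, j])
  if (!is.null(condition))
    use <- use[epochs40@condition[use] == condition]
  if (length(use) < minTrials)
    stop(sprintf("only %d usable trial(s); need >= %d", length(use),
                 minTrials))
  nWin <- length(idx)
  nfft <- 20 * rate                        # zero-pad to 20 s -> 0.05 Hz
  tap <- sineTapers(nWin, 2)
  freqIdx <- seq_len(round(fMax / (rate / nfft)) + 1L)
  freq <- (freqIdx - 1) * rate / nfft
  S <- array(complex(real = 0), dim = c(2, 2, length(freqIdx)))
  pad <- matrix(0, nfft - nWin, length(use))
  Xc <- vector("list", 2)
  for (k in 1:2) {
    coefs <- vector("list", 2)
    for (cc in 1:2) {
      ch <- c(i, j)[cc]
      seg <- t(matrix(epochs40@data[use, ch, idx], nrow = length(use)))
      coefs[[cc]] <- stats::mvfft(rbind(seg * tap[, k], pad))[freqIdx, ,
                                                              drop = FALSE]
    }
    for (a in 1:2) for (b in 1:2) {
      S[a, b, ] <- S[a, b, ] +
        rowMeans(coefs[[a]] * Conj(coefs[[b]]))
    }
  }
  S <- S / 2                               # average the two tapers
  structure(list(S = S, frequency = freq, nTrials = length(use),
                 nTapers = 2L, pair = epochs40@channels$name[c(i, j)],
                 period = period,
                 condition = if (is.null(condition)) "both" else condition),
            class = "CSDMatrix")
}

## Causal-part ("plus") operator over the full frequency circle:
## inverse FFT along frequency, keep positive lags and the upper-triangular
## half of the zero lag, zero the rest, FFT back.
.plusOperator <- function(g) {
  M <- dim(g)[3]
  gam <- array(complex(real = 0), dim = dim(g))
  for (a in 1:2) for (b in 1:2)
    gam[a, b, ] <- stats::fft(g[a, b, ], inverse = TRUE) / M
  keep <- array(complex(real = 0), dim = dim(g))
  g0 <- Re(gam[, , 1])
  half <- 0.5 * g0
  half[lower.tri(half)] <- 0               # triu of half the zero lag
  keep[, , 1] <- half
  pos <- 2:(M %/% 2)
  keep[, , pos] <- gam[, , pos]
  out <- array(complex(real = 0), dim = dim(g))
  for (a in 1:2) for (b in 1:2)
    out[a, b, ] <- stats::fft(keep[a, b, ])
  out
}

#' Wilson spectral-matrix factorization
#'
#' Iteratively factorizes the cross-spectral density S(f) = H(f) Sigma
#' H*(f) into a minimum-phase transfer function and a real innovation
#' covariance (Wilson's algorithm).  Initialization is the Cholesky
#' factor of the zero-lag covariance; convergence is declared when the
#' relative change of the factor between iterations falls below
#' \code{tol}.  Near-singular input spectra are regularized by adding
#' eps * I with eps = 1e-8 x the mean diagonal power (reported via a
#' message).
#'
#' @param csd a \code{CSDMatrix}.
#' @param tol relative convergence tolerance (default 1e-8).
#' @param maxIter maximum iterations (default 100); hitting it flags the
#'   result as non-converged rather than failing silently.
#' @return A list of class \code{SpectralFactorization}: \code{H}
#'   (2 x 2 x F), \code{Sigma} (2 x 2 real), \code{frequency},
#'   \code{residual} (max relative reconstruction error), \code{converged},
#'   \code{iterations}.
#' @export
wilsonFactorize <- function(csd, tol = 1e-8, maxIter = 100) {
  stopifnot(inherits(csd, "CSDMatrix"))
  S1 <- csd$S
  nF <- dim(S1)[3]
  ## regularize if any frequency is non-PSD
  minEig <- min(vapply(seq_len(nF), function(k)
    min(Re(eigen(S1[, , k], only.values = TRUE)$values)), 0))
  if (minEig < 0) {
    eps <- 1e-8 * mean(Re(S1[1, 1, ] + S1[2, 2, ])) / 2
    for (k in seq_len(nF)) S1[, , k] <- S1[, , k] + diag(eps, 2)
    message("CSD regularized: added ", format(eps), " * I")
    minEig2 <- min(vapply(seq_len(nF), function(k)
      min(Re(eigen(S1[, , k], only.values = TRUE)$values)), 0))
    if (minEig2 < 0) stop("CSD not positive semi-definite after regularization")
  }
  ## full circle: f = 0 .. rate, M = 2 (F - 1) points
  M <- 2L * (nF - 1L)
  Sf <- array(complex(real = 0), dim = c(2, 2, M))
  Sf[, , seq_len(nF)] <- S1
  for (k in 2:(nF - 1L)) Sf[, , M - k + 2L] <- Conj(S1[, , k])
  gam0 <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) gam0[a, b] <- Re(mean(Sf[a, b, ]))
  psi0 <- chol(gam0)                      # upper triangular, R^H R = gam0
  psi <- array(complex(real = 0), dim = c(2, 2, M))
  for (k in seq_len(M)) psi[, , k] <- psi0
  converged <- FALSE
  iter <- 0L
  ## all 2x2 algebra vectorized across the M frequencies
  s11 <- Sf[1, 1, ]; s12 <- Sf[1, 2, ]; s21 <- Sf[2, 1, ]; s22 <- Sf[2, 2, ]
  while (iter < maxIter) {
    iter <- iter + 1L
    p11 <- psi[1, 1, ]; p12 <- psi[1, 2, ]
    p21 <- psi[2, 1, ]; p22 <- psi[2, 2, ]
    det <- p11 * p22 - p12 * p21
    a11 <- p22 / det; a12 <- -p12 / det    # inv(psi)
    a21 <- -p21 / det; a22 <- p11 / det
    q11 <- a11 * s11 + a12 * s21; q12 <- a11 * s12 + a12 * s22
    q21 <- a21 * s11 + a22 * s21; q22 <- a21 * s12 + a22 * s22
    b11 <- Conj(a11); b21 <- Conj(a12)     # inv(psi)^H
    b12 <- Conj(a21); b22 <- Conj(a22)
    g <- array(complex(real = 0), dim = c(2, 2, M))
    g[1, 1, ] <- q11 * b11 + q12 * b21 + 1
    g[1, 2, ] <- q11 * b12 + q12 * b22
    g[2, 1, ] <- q21 * b11 + q22 * b21
    g[2, 2, ] <- q21 * b12 + q22 * b22 + 1
    gp <- .plusOperator(g)
    psiNew <- array(complex(real = 0), dim = c(2, 2, M))
    psiNew[1, 1, ] <- p11 * gp[1, 1, ] + p12 * gp[2, 1, ]
    psiNew[1, 2, ] <- p11 * gp[1, 2, ] + p12 * gp[2, 2, ]
    psiNew[2, 1, ] <- p21 * gp[1, 1, ] + p22 * gp[2, 1, ]
    psiNew[2, 2, ] <- p21 * gp[1, 2, ] + p22 * gp[2, 2, ]
    rel <- max(abs(psiNew - psi)) / max(max(abs(psi)), 1e-300)
    psi <- psiNew
    if (rel < tol) { converged <- TRUE; break }
  }
  A0 <- matrix(0, 2, 2)
  for (a in 1:2) for (b in 1:2) A0[a, b] <- Re(mean(psi[a, b, ]))
  Sigma <- A0 %*% t(A0)
  H <- array(complex(real = 0), dim = c(2, 2, nF))
  A0inv <- solve(A0)
  for (k in seq_len(nF)) H[, , k] <- psi[, , k] %*% A0inv
  frob <- function(m) sqrt(sum(Mod(m)^2))
  resid <- 0
  for (k in seq_len(nF)) {
    rec <- psi[, , k] %*% Conj(t(psi[, , k]))
    nrm <- frob(S1[, , k])
    if (nrm > 0) resid <- max(resid, frob(rec - S1[, , k]) / nrm)
  }
  if (!converged)
    warning(sprintf("Wilson factorization hit maxIter = %d (rel change %.2e)",
                    maxIter, rel))
  structure(list(H = H, Sigma = Sigma, frequency = csd$frequency,
                 residual = resid, converged = converged,
                 iterations = iter, pair = csd$pair, period = csd$period,
                 condition = csd$condition),
            class = "SpectralFactorization")
}

## Geweke spectral GC for both directions from a transfer function and
## innovation covariance; channels are (x, y) = pair[1], pair[2].
.gewekeGC <- function(H, Sigma, nF) {
  gc_yx <- numeric(nF)  # y -> x
  gc_xy <- numeric(nF)  # x -> y
  clipped <- FALSE
  for (k in seq_len(nF)) {
    Hk <- H[, , k]
    Sk <- Hk %*% Sigma %*% Conj(t(Hk))
    Sxx <- Re(Sk[1, 1]); Syy <- Re(Sk[2, 2])
    sig_y.x <- Sigma[2, 2] - Sigma[1, 2]^2 / Sigma[1, 1]
    sig_x.y <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
    intr_x <- Sxx - sig_y.x * Mod(Hk[1, 2])^2
    intr_y <- Syy - sig_x.y * Mod(Hk[2, 1])^2
    if (intr_x <= 0 || intr_y <= 0) {
      clipped <- TRUE
      intr_x <- max(intr_x, .Machine$double.eps * Sxx)
      intr_y <- max(intr_y, .Machine$double.eps * Syy)
    }
    gc_yx[k] <- log(Sxx / intr_x)
    gc_xy[k] <- log(Syy / intr_y)
  }
  if (clipped) warning("intrinsic power clipped at some frequency")
  gc_yx <- pmax(gc_yx, 0)
  gc_xy <- pmax(gc_xy, 0)
  list(gc_yx = gc_yx, gc_xy = gc_xy)
}

#' Spectral Granger causality from a factorized CSD
#'
#' Geweke's frequency-domain GC: GC_{Y->X}(f) = ln(Sxx(f) / intrinsic
#' Sxx(f)), where the intrinsic power removes the innovation contribution
#' routed through the cross transfer term (Sxx - (Sigma_yy -
#' Sigma_xy^2/Sigma_xx) |Hxy|^2).  Both directions are computed from the
#' reconstructed total power; values are non-negative up to numerical
#' clipping, and net GC is gc_yx - gc_xy (positive when channel 2 leads
#' channel 1).
#'
#' @param fact a \code{SpectralFactorization}.
#' @return data.frame of class \code{GCSpectrum}: frequency, gc_xy
#'   (pair[1] -> pair[2]), gc_yx (pair[2] -> pair[1]), net.
#' @export
spectralGC <- function(fact) {
  stopifnot(inherits(fact, "SpectralFactorization"))
  nF <- length(fact$frequency)
  gc <- .gewekeGC(fact$H, fact$Sigma, nF)
  out <- data.frame(frequency = fact$frequency, gc_xy = gc$gc_xy,
                    gc_yx = gc$gc_yx, net = gc$gc_yx - gc$gc_xy)
  attr(out, "pair") <- fact$pair
  attr(out, "period") <- fact$period
  attr(out, "condition") <- fact$condition
  class(out) <- c("GCSpectrum", "data.frame")
  out
}

#' Parametric spectral GC of a known VAR model (closed-form oracle)
#'
#' For a bivariate VAR with lag matrices \code{A} (list of 2 x 2) and
#' innovation covariance \code{Sigma}, the transfer function is H(f) =
#' (I - sum_k A_k e^(-2 pi i f k / rate))^(-1) and the spectral matrix
#' S = H Sigma H*; Geweke's GC follows in closed form.  This is an
#' independent reference for validating the non-parametric estimate.
#'
#' @param A list of 2 x 2 lag-coefficient matrices.
#' @param Sigma 2 x 2 innovation covariance.
#' @param freqs frequencies (Hz); @param rate sampling rate (Hz).
#' @return list: frequency, S (2 x 2 x F), H, gc_xy, gc_yx, net.
#' @export
parametricVARGC <- function(A, Sigma, freqs, rate) {
  nF <- length(freqs)
  H <- array(complex(real = 0), dim = c(2, 2, nF))
  S <- array(complex(real = 0), dim = c(2, 2, nF))
  for (k in seq_len(nF)) {
    z <- exp(-2i * pi * freqs[k] / rate * seq_along(A))
    Af <- diag(2) + 0i
    for (l in seq_along(A)) Af <- Af - A[[l]] * z[l]
    Hk <- solve(Af)
    H[, , k] <- Hk
    S[, , k] <- Hk %*% Sigma %*% Conj(t(Hk))
  }
  gc <- .gewekeGC(H, Sigma, nF)
  list(frequency = freqs, S = S, H = H, gc_xy = gc$gc_xy,
       gc_yx = gc$gc_yx, net = gc$gc_yx - gc$gc_xy)
}

#' Select peak frequency bands of the aggregate net GC
#'
#' Averages net-GC spectra over everything supplied, then greedily picks
#' local extrema of the mean net GC: the largest-magnitude extremum
#' first; its entire contiguous same-sign lobe is then masked, so further
#' extrema (magnitude >= \code{relMin} x the largest, up to
#' \code{maxPeaks}) must lie in different lobes -- one selected band per
#' direction lobe, never two points on one plateau.  Each selected range
#' is the extremum frequency +/- \code{halfWidth} Hz.  A flat spectrum
#' (maximum magnitude below \code{absMin}) yields an empty selection.
#'
#' @param netSpectra numeric matrix (spectra x frequencies) or vector of
#'   net GC values; rows are averaged.
#' @param frequencies frequency grid (Hz).
#' @param fRange analysis range (default 1-20 Hz).
#' @param halfWidth range half-width in Hz (default 1).
#' @param maxPeaks maximum number of ranges (default 2).
#' @param relMin secondary-peak magnitude threshold relative to the
#'   largest (default 0.5); @param absMin noise floor (default 1e-3).
#' @return data.frame: f_peak, sign, f_lo, f_hi (possibly 0 rows).
#' @export
selectPeakBand <- function(netSpectra, frequencies, fRange = c(1, 20),
                           halfWidth = 1, maxPeaks = 2, relMin = 0.5,
                           absMin = 1e-3) {
  m <- if (is.matrix(netSpectra)) colMeans(netSpectra) else netSpectra
  keep <- frequencies >= fRange[1] & frequencies <= fRange[2]
  f <- frequencies[keep]; m <- m[keep]
  out <- data.frame(f_peak = numeric(), sign = numeric(),
                    f_lo = numeric(), f_hi = numeric())
  if (max(abs(m)) < absMin) return(out)
  top <- max(abs(m))
  avail <- rep(TRUE, length(f))
  sgn <- sign(m)
  while (nrow(out) < maxPeaks && any(avail)) {
    k <- which(avail)[which.max(abs(m[avail]))]
    if (abs(m[k]) < max(relMin * top, absMin)) break
    out <- rbind(out, data.frame(
      f_peak = f[k], sign = sgn[k],
      f_lo = max(fRange[1], f[k] - halfWidth),
      f_hi = min(fRange[2], f[k] + halfWidth)))
    ## mask the extremum's contiguous same-sign lobe (plus halfWidth)
    lo <- k; while (lo > 1 && sgn[lo - 1] == sgn[k]) lo <- lo - 1
    hi <- k; while (hi < length(f) && sgn[hi + 1] == sgn[k]) hi <- hi + 1
    avail <- avail & !(seq_along(f) %in% lo:hi) &
      abs(f - f[k]) > halfWidth
  }
  out[order(out$f_peak), , drop = FALSE]
}

#' Period-averaged net GC over selected frequency ranges
#'
#' @param gcTable long data.frame with columns patient, pair_id, period,
#'   condition, frequency, net (recall never present: the GC stage
#'   excludes it).
#' @param ranges data.frame with f_lo, f_hi (Hz, inclusive).
#' @return data.frame: range, patient, pair_id, period, condition,
#'   mean_net_gc.
#' @export
averageNetGCPeriods <- function(gcTable, ranges) {
  if (nrow(ranges) == 0) stop("no selected frequency ranges")
  out <- list()
  for (r in seq_len(nrow(ranges))) {
    sel <- gcTable$frequency >= ranges$f_lo[r] &
      gcTable$frequency <= ranges$f_hi[r]
    ag <- stats::aggregate(net ~ patient + pair_id + period + condition,
                           data = gcTable[sel, ], FUN = mean)
    names(ag)[names(ag) == "net"] <- "mean_net_gc"
    ag$range <- sprintf("%g-%gHz", ranges$f_lo[r], ranges$f_hi[r])
    out[[r]] <- ag
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
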