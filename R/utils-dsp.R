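## Shared signal-processing primitives: zero-phase Butterworth filtering,
## FFT analytic signal, taper families, anti-aliased decimation.

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter with \code{signal::butter} and applies it
#' forward-backward (\code{signal::filtfilt}), doubling the effective order
#' and cancelling phase shift.  \code{order} is the prototype order, so a
#' band filter of prototype order n has transfer-function order 2n (the
#' usual "nth order Butterworth band-stop" convention counts the
#' prototype).
#'
#' @param x numeric vector or channels x time matrix.
#' @param rate sampling rate (Hz).
#' @param band numeric length-2 corner frequencies (Hz); for low/high pass
#'   a single number.
#' @param type "pass", "stop", "low" or "high".
#' @param order prototype filter order.
#' @return Filtered data, same shape as \code{x}.
#' @keywords internal
butterFiltfilt <- function(x, rate, band, type = "pass", order = 3) {
  w <- band / (rate / 2)
  if (any(w <= 0) || any(w >= 1))
    stop("filter corner frequencies must lie strictly inside (0, Nyquist)")
  flt <- signal::butter(order, w, type = type)
  if (is.matrix(x)) {
    t(apply(x, 1, function(row) signal::filtfilt(flt, row)))
  } else {
    signal::filtfilt(flt, x)
  }
}

#' Analytic signal via FFT
#'
#' Returns the complex analytic signal (positive-frequency half spectrum
#' doubled, negative zeroed); its modulus is the amplitude envelope.
#'
#' @param x real numeric vector.
#' @return complex vector, same length.
#' @keywords internal
analyticSignal <- function(x) {
  n0 <- length(x)
  ## pad to a 2-3-5-smooth length (mixed-radix FFT is pathological on
  ## large prime lengths); reflect the tail so the pad has no step edge
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) {
    pad <- n - n0
    tail <- x[n0:max(1, n0 - pad + 1)]
    x <- c(x, rep(tail, length.out = pad))
  }
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

## DPSS (Slepian) tapers from the symmetric tridiagonal formulation.
## Cached per (n, nw, k) because the eigendecomposition dominates cost.
.taperCache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first \code{k} DPSS tapers of length \code{n} with
#' time-bandwidth product \code{nw}, via the classical tridiagonal
#' eigenproblem.  Tapers are unit-energy and sign-fixed so each taper's
#' mean (first taper) or first lobe is positive.
#'
#' @param n taper length (samples).
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @return n x k matrix of tapers, columns ordered by decreasing
#'   concentration.
#' @keywords internal
dpssTapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.taperCache[[key]])) return(.taperCache[[key]])
  w <- nw / n
  t0 <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  A <- matrix(0, n, n)
  A[cbind(1:n, 1:n)] <- diag_main
  A[cbind(1:(n - 1), 2:n)] <- diag_off
  A[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(A, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  .taperCache[[key]] <- tap
  tap
}

#' Orthogonal sine tapers
#'
#' The k-th sine taper is sqrt(2/(n+1)) sin(pi k (1:n)/(n+1)); the first
#' two form the 2-taper Hann-like orthogonal family used for the
#' cross-spectral stage.
#'
#' @param n taper length; @param k number of tapers.
#' @return n x k matrix, unit-energy columns.
#' @keywords internal
sineTapers <- function(n, k) {
  tt <- seq_len(n)
  sapply(seq_len(k), function(j) sqrt(2 / (n + 1)) * sin(pi * j * tt / (n + 1)))
}

#' Anti-aliased decimation
#'
#' Zero-phase Butterworth low-pass at 0.8 x the target Nyquist followed by
#' picking every \code{factor}-th sample (starting at the first).
#'
#' @param x numeric vector; @param rate input rate (Hz);
#' @param factor integer decimation factor.
#' @return decimated vector at rate/factor Hz.
#' @keywords internal
decimateSignal <- function(x, rate, factor) {
  stopifnot(factor == round(factor), factor >= 1)
  if (factor == 1) return(x)
  newNyq <- rate / factor / 2
  y <- butterFiltfilt(x, rate, 0.8 * newNyq, type = "low", order = 4)
  y[seq(1, length(y), by = factor)]
}

#' Band-limited resampling to an arbitrary rate
#'
#' Zero-phase Butterworth anti-alias low-pass (order 6, cutoff 0.95 x the
#' target Nyquist) followed by cubic-spline interpolation onto the new
#' uniform grid t = (0:(m-1))/newRate aligned with the first input sample.
#'
#' @param x numeric vector; @param rate input rate; @param newRate target
#'   rate (Hz, < rate).
#' @return numeric vector of floor(length(x) * newRate / rate) samples.
#' @keywords internal
resampleSignal <- function(x, rate, newRate) {
  stopifnot(newRate < rate)
  y <- butterFiltfilt(x, rate, 0.95 * newRate / 2, type = "low", order = 6)
  n <- length(x)
  m <- floor(n * newRate / rate)
  tOld <- (seq_len(n) - 1) / rate
  tNew <- (seq_len(m) - 1) / newRate
  stats::spline(tOld, y, xout = tNew, method = "natural")$y
}

#' Von Mises random deviates
#'
#' Best-Fisher (1979) rejection sampler.  Used for the simulator's phase
#' jitter; the mean resultant length of VM(mu, kappa) is
#' besselI(kappa, 1) / besselI(kappa, 0), which is the generator's
#' closed-form PLV target.
#'
#' @param n number of deviates; @param mu mean direction (radians);
#' @param kappa concentration (>= 0).
#' @return numeric vector of angles in (-pi, pi].
#' @keywords internal
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  ang <- out + mu
  atan2(sin(ang), cos(ang))
}

## 1/f^alpha coloured noise via FFT spectral shaping (unit SD).
colouredNoise <- function(n, exponent = 1, rate = 512) {
  m <- stats::nextn(n, c(2, 3, 5))   # keep the FFT on a smooth length
  white <- stats::rnorm(m)
  X <- stats::fft(white)
  f <- c(0, seq_len(m - 1)) / m * rate
  f <- pmin(f, rate - f)
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}
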