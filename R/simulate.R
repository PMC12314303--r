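## Synthetic iEEG session generator with known ground truth.
##
## Contacts are built so that bipolar derivation (next minus current
## contact on a shaft) recovers exactly the configured per-channel signal:
## contact j carries the cumulative sum of the first j-1 channel signals
## plus its own 1/f background, so B_k = C_{k+1} - C_k = s_k + (bg_{k+1} -
## bg_k).  Power effects, Von Mises phase coupling and lagged directed
## coupling are therefore injected per *bipolar* channel with exact
## bookkeeping.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the task: 80 trials per
#' condition in counterbalanced 10-trial blocks, fixation jittered
#' U(1.9, 2.1) s, encoding 2.0 s, delay U(3.9, 4.1) s, action 2.0 s, plus
#' a 2.0 s identity question for "different"-condition trials; 512 Hz
#' sampling; 1/f background with 50 Hz line noise and interictal spikes.
#'
#' @param nTrialsPerCondition trials per condition (default 80).
#' @param blockSize trials per block (default 10); must divide the trial
#'   count and yield an even number of block pairs.
#' @param channelsPerRegion named integer vector of *bipolar* channels per
#'   region; each region occupies one shaft with one extra contact.
#' @param rate sampling rate, Hz.
#' @param backgroundExponent power-law exponent of the background power
#'   spectrum (power ~ 1/f^exponent; default 1.5, typical of intracranial
#'   field potentials).
#' @param backgroundScale background SD per bipolar channel, microvolts.
#' @param lineNoiseAmplitude 50 Hz line amplitude surviving bipolar
#'   derivation, microvolts (a 100 Hz harmonic at 30\% is added).
#' @param spikeRate interictal spike events per minute across all shafts.
#' @param bandEffects list of effects, each a list with fields
#'   \code{region}, \code{band} (Hz range), \code{periods} (task-period
#'   names), \code{condition} ("same"/"different"/"both"), \code{change}
#'   (multiplicative amplitude change in the period) and optional
#'   \code{amplitude} (baseline oscillator amplitude, microvolts).
#' @param couplings list of couplings, each a list with fields
#'   \code{regions} (length-2), \code{frequency} (Hz, must be <= 20),
#'   \code{periods}, \code{condition}, \code{kappa} (Von Mises
#'   concentration; expected PLV is I1(kappa)/I0(kappa)), optional
#'   \code{amplitude}, and for directed coupling \code{direction}
#'   (length-2: from, to), \code{lagMs} and \code{strength}.
#' @param behavioralAccuracy named vector, probabilities of a correct
#'   position / identity response.
#' @param hemisphere implant hemisphere label.
#' @param interBlockGap break between blocks, seconds.
#' @param sessionPad quiet padding at session start/end, seconds.
#' @param seed default RNG seed for \code{simulateSession}.
#' @return A list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nTrialsPerCondition = 80,
                             blockSize = 10,
                             channelsPerRegion = c(IPL = 4, VTC = 4, HIP = 3),
                             rate = 512,
                             backgroundExponent = 1.5,
                             backgroundScale = 30,
                             lineNoiseAmplitude = 4,
                             spikeRate = 2,
                             bandEffects = list(),
                             couplings = list(),
                             behavioralAccuracy = c(position = 0.98,
                                                    identity = 0.91),
                             hemisphere = "R",
                             interBlockGap = 4,
                             sessionPad = 4,
                             seed = 1L) {
  nTotal <- 2 * nTrialsPerCondition
  if (nTotal %% blockSize != 0)
    stop("blockSize must divide the total trial count")
  nBlocks <- nTotal / blockSize
  if (nBlocks %% 2 != 0)
    stop("need an even number of blocks to counterbalance the two orders")
  for (cp in couplings) {
    if (cp$frequency > 20)
      stop("coupling frequency must be <= 20 Hz (half the 40 Hz GC rate)")
    if (!is.null(cp$kappa) && cp$kappa < 0) stop("kappa must be >= 0")
  }
  structure(list(
    nTrialsPerCondition = nTrialsPerCondition, blockSize = blockSize,
    channelsPerRegion = channelsPerRegion, rate = rate,
    backgroundExponent = backgroundExponent,
    backgroundScale = backgroundScale,
    lineNoiseAmplitude = lineNoiseAmplitude, spikeRate = spikeRate,
    bandEffects = bandEffects, couplings = couplings,
    behavioralAccuracy = behavioralAccuracy, hemisphere = hemisphere,
    interBlockGap = interBlockGap, sessionPad = sessionPad,
    seed = as.integer(seed)), class = "SimulationConfig")
}

#' Counterbalanced trial schedule
#'
#' Blocks of \code{blockSize} trials alternate between conditions in
#' counterbalanced pairs (equally many same-then-different and
#' different-then-same pairs, in shuffled order).  Fixation is drawn
#' U(1.9, 2.1) s and delay U(3.9, 4.1) s per trial; encoding and action
#' are fixed at 2.0 s and the question phase (different condition only) at
#' 2.0 s, so total trial durations span 9.8-10.2 s (same) and 11.8-12.2 s
#' (different).  Behavioral correctness flags are drawn at the configured
#' accuracies.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param seed RNG seed (defaults to \code{cfg$seed}).
#' @return Events data.frame (see \code{\link{readEvents}}).
#' @export
scheduleTrials <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  nBlocks <- 2 * cfg$nTrialsPerCondition / cfg$blockSize
  pairOrders <- sample(rep(c("sd", "ds"), length.out = nBlocks / 2))
  blockCond <- unlist(lapply(pairOrders, function(p)
    if (p == "sd") c("same", "different") else c("different", "same")))
  n <- 2 * cfg$nTrialsPerCondition
  condition <- rep(blockCond, each = cfg$blockSize)
  block_index <- rep(seq_len(nBlocks), each = cfg$blockSize)
  fixation_s <- stats::runif(n, 1.9, 2.1)
  encoding_s <- rep(2.0, n)
  delay_s <- stats::runif(n, 3.9, 4.1)
  action_s <- rep(2.0, n)
  question_s <- ifelse(condition == "different", 2.0, NA_real_)
  trialLen <- fixation_s + encoding_s + delay_s + action_s +
    ifelse(is.na(question_s), 0, question_s)
  gapAfter <- c(ifelse(diff(block_index) > 0, cfg$interBlockGap, 0), 0)
  trialStart <- cfg$sessionPad + c(0, cumsum((trialLen + gapAfter)[-n]))
  onset <- trialStart + fixation_s
  correct_position <- stats::runif(n) < cfg$behavioralAccuracy[["position"]]
  correct_identity <- ifelse(
    condition == "different",
    stats::runif(n) < cfg$behavioralAccuracy[["identity"]], NA)
  ev <- data.frame(onset = onset, condition = condition,
                   block_index = block_index, fixation_s = fixation_s,
                   encoding_s = encoding_s, delay_s = delay_s,
                   action_s = action_s, question_s = question_s,
                   correct_position = correct_position,
                   correct_identity = correct_identity)
  validateEvents(ev)
}

## Task-period injection windows in session time: (start, duration).
## delay1/delay2 skip the jittered 0.2 s head of the delay phase, matching
## the epoch layout.
.periodWindow <- function(ev, i, period) {
  on <- ev$onset[i]
  switch(period,
    baseline = c(on - 1.9, 1.9),
    encoding = c(on, 2.0),
    delay1   = c(on + 2.0 + 0.2, 1.9),
    delay2   = c(on + 2.0 + 0.2 + 1.9, 1.9),
    recall   = c(on + 2.0 + ev$delay_s[i], 2.0),
    stop("unknown period: ", period))
}

.ramp <- function(nSamp, rate, rampS = 0.05) {
  w <- rep(1, nSamp)
  nr <- min(round(rampS * rate), floor(nSamp / 2))
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    w[seq_len(nr)] <- up
    w[nSamp + 1 - seq_len(nr)] <- rev(up)
  }
  w
}

.matchCondition <- function(trialCond, effCond) {
  if (is.null(effCond) || identical(effCond, "both")) rep(TRUE, length(trialCond))
  else trialCond %in% effCond
}

#' Expected PLV of a Von Mises phase jitter
#'
#' The mean resultant length of VM(mu, kappa):
#' \code{besselI(kappa, 1) / besselI(kappa, 0)}.
#'
#' @param kappa concentration parameter (>= 0).
#' @return expected PLV in [0, 1).
#' @export
vonMisesPLV <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

#' Simulate a full task session
#'
#' Generates contact-level signals (1/f background, line noise, interictal
#' spikes) plus the configured band-power effects, Von Mises phase
#' couplings and lagged directed couplings, realized per bipolar channel
#' (see the file header note on the cumulative contact construction).
#' Identical (cfg, seed) pairs give bit-identical output.
#'
#' @param cfg a \code{SimulationConfig}.
#' @param seed RNG seed (defaults to \code{cfg$seed}).
#' @return A list with elements \code{recording}
#'   (\linkS4class{ContinuousRecording} of contacts), \code{events}
#'   (data.frame) and \code{truth} (list of class \code{GroundTruth} with
#'   elements \code{channels} -- the bipolar channel names per region --,
#'   \code{bandEffects}, \code{couplings} (with \code{plvTarget}),
#'   \code{spikes} and \code{config}).
#' @export
simulateSession <- function(cfg, seed = cfg$seed) {
  ev <- scheduleTrials(cfg, seed = seed)
  set.seed(seed + 1L)
  rate <- cfg$rate
  nTrials <- nrow(ev)
  sessionEnd <- max(ev$onset + ev$encoding_s + ev$delay_s + ev$action_s +
                      ifelse(is.na(ev$question_s), 0, ev$question_s)) +
    cfg$sessionPad
  n <- ceiling(sessionEnd * rate)

  regions <- names(cfg$channelsPerRegion)
  shaftOf <- function(r) paste0(cfg$hemisphere, substr(r, 1, 2))
  ## bipolar-channel bookkeeping
  chan <- do.call(rbind, lapply(regions, function(r) {
    m <- cfg$channelsPerRegion[[r]]
    data.frame(region = r, shaft = shaftOf(r), idx = seq_len(m),
               name = paste0(shaftOf(r), seq_len(m), "-",
                             shaftOf(r), seq_len(m) + 1L))
  }))
  nChan <- nrow(chan)

  ## per-bipolar-channel injected signal
  sig <- matrix(0, nChan, n)

  effectRows <- list()
  for (eff in cfg$bandEffects) {
    chIdx <- which(chan$region == eff$region)
    amp <- if (is.null(eff$amplitude)) 12 else eff$amplitude
    f0 <- mean(eff$band)
    for (ch in chIdx) {
      carrier <- butterFiltfilt(stats::rnorm(n), rate, eff$band,
                                type = "pass", order = 3)
      carrier <- carrier / stats::sd(carrier)
      gain <- rep(1, n)
      hit <- .matchCondition(ev$condition, eff$condition)
      for (i in which(hit)) for (p in eff$periods) {
        w <- .periodWindow(ev, i, p)
        i0 <- round(w[1] * rate) + 1L
        len <- floor(w[2] * rate)
        idx <- i0:(i0 + len - 1L)
        gain[idx] <- 1 + (eff$change - 1) * .ramp(len, rate)
      }
      sig[ch, ] <- sig[ch, ] + amp * gain * carrier
      effectRows[[length(effectRows) + 1L]] <- data.frame(
        channel = chan$name[ch], region = eff$region,
        band_lo = eff$band[1], band_hi = eff$band[2],
        periods = paste(eff$periods, collapse = ","),
        condition = if (is.null(eff$condition)) "both" else
          paste(eff$condition, collapse = ","),
        change = eff$change, frequency = f0)
    }
  }

  couplingRows <- list()
  for (cp in cfg$couplings) {
    rA <- cp$regions[1]; rB <- cp$regions[2]
    amp <- if (is.null(cp$amplitude)) 10 else cp$amplitude
    kappa <- if (is.null(cp$kappa)) 0 else cp$kappa
    chA <- which(chan$region == rA)
    chB <- which(chan$region == rB)
    hit <- .matchCondition(ev$condition, cp$condition)
    directed <- !is.null(cp$direction) && !is.null(cp$strength) &&
      cp$strength > 0
    for (i in which(hit)) for (p in cp$periods) {
      w <- .periodWindow(ev, i, p)
      i0 <- round(w[1] * rate) + 1L
      len <- floor(w[2] * rate)
      idx <- i0:(i0 + len - 1L)
      tt <- (seq_len(len) - 1) / rate
      wdw <- .ramp(len, rate)
      phi <- stats::runif(1, 0, 2 * pi)
      if (kappa > 0) {
        srcSeg <- amp * wdw * cos(2 * pi * cp$frequency * tt + phi)
        for (a in chA) sig[a, idx] <- sig[a, idx] + srcSeg
        for (b in chB) {
          dphi <- rvonmises(1, 0, kappa)
          sig[b, idx] <- sig[b, idx] +
            amp * wdw * cos(2 * pi * cp$frequency * tt + phi + dphi)
        }
      }
      if (directed) {
        lag <- round(cp$lagMs / 1000 * rate)
        bw <- max(1, if (is.null(cp$bandwidth)) 1 else cp$bandwidth)
        uFull <- butterFiltfilt(stats::rnorm(len + lag), rate,
                                c(max(0.5, cp$frequency - bw),
                                  cp$frequency + bw), type = "pass",
                                order = 3)
        uFull <- uFull / stats::sd(uFull)
        uNow <- uFull[(lag + 1):(lag + len)]
        uLag <- uFull[seq_len(len)]
        fromCh <- which(chan$region == cp$direction[1])
        toCh <- which(chan$region == cp$direction[2])
        for (a in fromCh) sig[a, idx] <- sig[a, idx] + amp * wdw * uNow
        for (b in toCh) sig[b, idx] <- sig[b, idx] +
          amp * cp$strength * wdw * uLag
      }
    }
    couplingRows[[length(couplingRows) + 1L]] <- data.frame(
      region_a = rA, region_b = rB, frequency = cp$frequency,
      kappa = kappa, plvTarget = if (kappa > 0) vonMisesPLV(kappa) else NA,
      periods = paste(cp$periods, collapse = ","),
      condition = if (is.null(cp$condition)) "both" else
        paste(cp$condition, collapse = ","),
      direction = if (directed) paste(cp$direction, collapse = "->") else "",
      lagMs = if (directed) cp$lagMs else NA,
      strength = if (directed) cp$strength else NA)
  }

  ## assemble contacts: C_j = sum_{k<j} s_k + background_j (+ line, spikes)
  contacts <- list()
  contactTab <- list()
  spikeRows <- list()
  tAll <- (seq_len(n) - 1) / rate
  line50 <- sin(2 * pi * 50 * tAll)
  line100 <- sin(2 * pi * 100 * tAll + 0.7)
  ## 70 ms biphasic spike-and-wave: sharp ~16 ms component followed by a
  ## slower opposite-polarity wave; peak normalized to 1
  spikeLen <- round(0.070 * rate)
  tSpike <- seq_len(spikeLen) / rate
  spikeShape <- exp(-((tSpike - 0.018) / 0.008)^2) -
    0.55 * exp(-((tSpike - 0.045) / 0.020)^2)
  spikeShape <- spikeShape / max(abs(spikeShape))
  for (r in regions) {
    m <- cfg$channelsPerRegion[[r]]
    sh <- shaftOf(r)
    chIdx <- which(chan$region == r)
    cum <- matrix(0, m + 1L, n)
    for (j in seq_len(m)) cum[j + 1L, ] <- cum[j, ] + sig[chIdx[j], ]
    for (j in seq_len(m + 1L)) {
      bg <- cfg$backgroundScale / sqrt(2) *
        colouredNoise(n, cfg$backgroundExponent, rate)
      ln <- cfg$lineNoiseAmplitude * (j - 1) *
        (line50 + 0.3 * line100)
      contacts[[paste0(sh, j)]] <- cum[j, ] + bg + ln
      contactTab[[paste0(sh, j)]] <- data.frame(
        name = paste0(sh, j), shaft = sh, contact_index = j,
        region = r, hemisphere = cfg$hemisphere, bad = FALSE, soz = FALSE)
    }
    ## interictal spikes on this shaft
    nSpk <- stats::rpois(1, cfg$spikeRate * (n / rate / 60) / length(regions))
    if (nSpk > 0) {
      spkT <- sort(stats::runif(nSpk, 1, n / rate - 1))
      spkC <- sample(m + 1L, nSpk, replace = TRUE)
      for (s in seq_len(nSpk)) {
        i0 <- round(spkT[s] * rate)
        ampS <- cfg$backgroundScale * stats::runif(1, 5, 10)
        nm <- paste0(sh, spkC[s])
        contacts[[nm]][i0:(i0 + spikeLen - 1L)] <-
          contacts[[nm]][i0:(i0 + spikeLen - 1L)] + ampS * spikeShape
        spikeRows[[length(spikeRows) + 1L]] <- data.frame(
          time = spkT[s], contact = nm, shaft = sh,
          contact_index = spkC[s])
      }
    }
  }
  contactTab <- do.call(rbind, c(contactTab, make.row.names = FALSE))
  x <- do.call(rbind, contacts)
  rec <- new("ContinuousRecording", samples = x, rate = rate,
             channels = contactTab,
             sessionId = sprintf("sim-seed%d", seed))
  truth <- structure(list(
    channels = split(chan$name, chan$region),
    channelTable = chan[, c("name", "region", "shaft", "idx")],
    bandEffects = if (length(effectRows)) do.call(rbind, effectRows) else
      data.frame(),
    couplings = if (length(couplingRows)) do.call(rbind, couplingRows) else
      data.frame(),
    spikes = if (length(spikeRows)) do.call(rbind, spikeRows) else
      data.frame(time = numeric(), contact = character(),
                 shaft = character(), contact_index = integer()),
    config = cfg, seed = seed), class = "GroundTruth")
  list(recording = rec, events = ev, truth = truth)
}

#' Score a joystick reach trajectory
#'
#' A response is correct when any trajectory point falls inside the
#' axis-aligned square centred on the target with half-width
#' \code{halfMinDistance} (boundary inclusive; default 0.105 of screen
#' width, half the minimum between-object distance).  Reaction time is
#' the time of first entry.
#'
#' @param trajectory n x 2 matrix (or data.frame) of (x, y) screen
#'   fractions.
#' @param targetXY length-2 target position.
#' @param halfMinDistance square half-width (screen fraction, > 0).
#' @param times optional per-point times (s from action onset); defaults
#'   to 0-based sample index at 60 Hz.
#' @return list with \code{correct} (logical) and \code{reactionTime}
#'   (s of first entry, NA when incorrect).
#' @export
scoreResponse <- function(trajectory, targetXY, halfMinDistance = 0.105,
                          times = NULL) {
  trajectory <- as.matrix(trajectory)
  if (nrow(trajectory) == 0) stop("trajectory must be non-empty")
  if (halfMinDistance <= 0) stop("halfMinDistance must be > 0")
  if (is.null(times)) times <- (seq_len(nrow(trajectory)) - 1) / 60
  inside <- abs(trajectory[, 1] - targetXY[1]) <= halfMinDistance &
    abs(trajectory[, 2] - targetXY[2]) <= halfMinDistance
  if (any(inside)) {
    list(correct = TRUE, reactionTime = times[which(inside)[1]])
  } else {
    list(correct = FALSE, reactionTime = NA_real_)
  }
}
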