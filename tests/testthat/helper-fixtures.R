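## Shared fixtures: all synthetic, built in code at test time.

mkChannels <- function(n, shaft = "A", region = "IPL", hemisphere = "R",
                       bad = rep(FALSE, n), soz = rep(FALSE, n)) {
  data.frame(name = paste0(shaft, seq_len(n)), shaft = shaft,
             contact_index = seq_len(n), region = region,
             hemisphere = hemisphere, bad = bad, soz = soz,
             stringsAsFactors = FALSE)
}

mkRecording <- function(x, rate = 512, channels = NULL, id = "test") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(channels)) channels <- mkChannels(nrow(x))
  new("ContinuousRecording", samples = x, rate = rate,
      channels = channels, sessionId = id)
}

## one-trial (or n-trial) event table with fixed jitters
mkEvents <- function(n = 1, onset0 = 10, gap = 12, fixation = 2.0,
                     delay = 4.0, condition = rep("same", n)) {
  onset <- onset0 + (seq_len(n) - 1) * gap
  data.frame(onset = onset, condition = condition,
             block_index = rep(1L, n), fixation_s = rep(fixation, n),
             encoding_s = 2.0, delay_s = rep(delay, n), action_s = 2.0,
             question_s = ifelse(condition == "different", 2.0, NA_real_),
             correct_position = TRUE,
             correct_identity = ifelse(condition == "different", TRUE, NA))
}

## EpochSet built directly from an array (trials x channels x time); the
## time dimension must match the fixed epoch layout for (rate, baseline)
mkEpochSet <- function(arr, rate = 512, baselineLength = 1.9,
                       condition = NULL, channels = NULL) {
  nT <- dim(arr)[1]; nC <- dim(arr)[2]
  counts <- streamsync:::.segmentCounts(rate, baselineLength)
  stopifnot(dim(arr)[3] == sum(counts))
  if (is.null(condition))
    condition <- factor(rep(c("same", "different"), length.out = nT),
                        levels = c("same", "different"))
  if (is.null(channels)) channels <- mkChannels(nC)
  new("EpochSet", data = arr, rate = rate,
      window = c(-baselineLength, 7.8),
      periods = streamsync:::.periodTable(baselineLength),
      condition = condition, channels = channels,
      excluded = matrix(FALSE, nT, nC),
      reason = matrix("", nT, nC))
}

## epoch sample count for (rate, baseline)
epochLen <- function(rate, baselineLength) {
  sum(streamsync:::.segmentCounts(rate, baselineLength))
}

## EnvelopeSet built directly (64 Hz grid, 0.5 s baseline window)
mkEnvelopeSet <- function(arr, condition = NULL, band = "alpha",
                          baselined = FALSE, channels = NULL) {
  nT <- dim(arr)[1]; nC <- dim(arr)[2]
  stopifnot(dim(arr)[3] == epochLen(64, 0.5))
  if (is.null(condition))
    condition <- factor(rep(c("same", "different"), length.out = nT),
                        levels = c("same", "different"))
  if (is.null(channels)) channels <- mkChannels(nC)
  new("EnvelopeSet", values = arr, band = band,
      bandRange = unlist(streamsync:::BAND_RANGES[[band]]), rate = 64,
      window = c(-0.5, 7.8),
      periods = streamsync:::.periodTable(0.5), condition = condition,
      channels = channels, excluded = matrix(FALSE, nT, nC),
      baselined = baselined)
}

## TrialSpectra with one taper and unit-magnitude coefficients from given
## phase arrays (trials x frequencies) per channel -- an exact oracle
## input for the PLV formula
mkSpectraFromPhases <- function(phaseList, freqs = 2:20,
                                period = "delay1") {
  nT <- nrow(phaseList[[1]]); nC <- length(phaseList); nF <- ncol(phaseList[[1]])
  stopifnot(nF == length(freqs))
  co <- array(complex(real = 0), dim = c(nT, 1, nC, nF))
  for (c in seq_len(nC))
    co[, 1, c, ] <- exp(1i * phaseList[[c]])
  new("TrialSpectra", coefficients = co, frequencies = as.numeric(freqs),
      period = period, windowLength = 1.9,
      condition = factor(rep("same", nT),
                         levels = c("same", "different")),
      channels = mkChannels(nC), excluded = matrix(FALSE, nT, nC))
}

## stable bivariate VAR simulator (time-domain) for Monte-Carlo CSD tests
simVAR <- function(A, Sigma, n, burn = 200) {
  p <- length(A)
  L <- t(chol(Sigma))
  x <- matrix(0, 2, n + burn + p)
  for (t in (p + 1):(n + burn + p)) {
    e <- L %*% rnorm(2)
    acc <- e
    for (l in seq_len(p)) acc <- acc + A[[l]] %*% x[, t - l]
    x[, t] <- acc
  }
  x[, (burn + p + 1):(burn + p + n)]
}

## 40 Hz GC-grid epochs from per-trial generator function gen(trialIndex)
## returning a 2 x nSamples matrix
mkEpochs40 <- function(nTrials, gen, channels = NULL) {
  counts <- streamsync:::.segmentCounts(40, 1.9)
  nS <- sum(counts)
  arr <- array(0, dim = c(nTrials, 2, nS))
  for (i in seq_len(nTrials)) arr[i, , ] <- gen(i)
  if (is.null(channels))
    channels <- rbind(mkChannels(1, shaft = "A", region = "IPL"),
                      mkChannels(1, shaft = "B", region = "VTC"))
  channels$name <- c("chA", "chB")
  mkEpochSet(arr, rate = 40, baselineLength = 1.9, channels = channels)
}

## simulate a period-mean table from the model's own equation
simLMMTable <- function(nPatients = 6, nUnits = 8, sdPatient = 5,
                        sdUnit = 5, sdNoise = 8, delay1 = 30,
                        interactionDelay1 = -15, intercept = 5) {
  tab <- expand.grid(
    patient = paste0("P", seq_len(nPatients)),
    channel = paste0("ch", seq_len(nUnits)),
    period = c("baseline", "encoding", "delay1", "delay2", "recall"),
    condition = c("same", "different"), stringsAsFactors = FALSE)
  tab$channel <- paste(tab$patient, tab$channel)
  up <- rnorm(nPatients, 0, sdPatient)
  uc <- rnorm(nPatients * nUnits, 0, sdUnit)
  tab$mean_power <- intercept +
    ifelse(tab$period == "delay1", delay1, 0) +
    ifelse(tab$period == "delay1" & tab$condition == "different",
           interactionDelay1, 0) +
    up[as.integer(factor(tab$patient))] +
    uc[as.integer(factor(tab$channel))] +
    rnorm(nrow(tab), 0, sdNoise)
  tab
}
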