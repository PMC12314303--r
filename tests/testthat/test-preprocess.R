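test_that("notch filter removes line components and spares neighbours", {
  t <- (0:(512 * 10 - 1)) / 512
  rec50 <- mkRecording(matrix(sin(2 * pi * 50 * t), 1))
  out50 <- samples(notchFilter(rec50))[1, ]
  mid <- 1000:4000
  expect_lt(max(abs(out50[mid])), 0.05)              # < 5 % residual
  rec10 <- mkRecording(matrix(sin(2 * pi * 10 * t), 1))
  out10 <- samples(notchFilter(rec10))[1, ]
  expect_lt(max(abs(out10[mid] - sin(2 * pi * 10 * t)[mid])), 0.01)
  rec45 <- mkRecording(matrix(sin(2 * pi * 45 * t), 1))
  out45 <- samples(notchFilter(rec45))[1, ]
  ## passband amplitude distortion < 1 % at 45 Hz
  expect_lt(abs(max(abs(out45[mid])) - 1), 0.01)
  recZ <- mkRecording(matrix(0, 1, 5120))
  expect_true(all(samples(notchFilter(recZ)) == 0))
  ## harmonics are also attenuated
  rec150 <- mkRecording(matrix(sin(2 * pi * 150 * t), 1))
  expect_lt(max(abs(samples(notchFilter(rec150))[1, mid])), 0.05)
})

test_that("bipolar derivation counts pairs and rejects common-mode", {
  set.seed(2)
  n <- 2048
  x <- matrix(rnorm(8 * n), 8)
  rec <- mkRecording(x, channels = mkChannels(8))
  bp <- bipolarReference(rec)
  expect_equal(nrow(samples(bp)), 7)                 # 8 contacts -> 7
  expect_equal(samples(bp)[1, ], x[2, ] - x[1, ])
  ## identical common signal on all contacts cancels exactly
  common <- matrix(rep(rnorm(n), each = 8), 8, byrow = FALSE)
  bp2 <- bipolarReference(mkRecording(x + common, channels = mkChannels(8)))
  expect_equal(samples(bp2), samples(bp), tolerance = 1e-12)
  ## contact 3 flagged soz: pairs (2,3) and (3,4) removed, 5 remain
  soz <- rep(FALSE, 8); soz[3] <- TRUE
  bp3 <- bipolarReference(mkRecording(x, channels = mkChannels(8, soz = soz)))
  expect_equal(nrow(samples(bp3)), 5)
  expect_false(any(grepl("A3", channelTable(bp3)$name)))
  ## deeper contact's region labels the pair
  ch <- mkChannels(3)
  ch$region <- c("IPL", "VTC", "VTC")
  bp4 <- bipolarReference(mkRecording(x[1:3, ], channels = ch))
  expect_equal(channelTable(bp4)$region, c("IPL", "VTC"))
  ## shaft with < 2 usable contacts is dropped with a warning
  twoShafts <- rbind(mkChannels(2, shaft = "A", bad = c(TRUE, FALSE)),
                     mkChannels(2, shaft = "B"))
  bp5 <- NULL
  expect_warning(
    bp5 <- bipolarReference(mkRecording(x[1:4, ], channels = twoShafts)),
    "fewer than 2")
  expect_equal(channelTable(bp5)$shaft, "B")
})

test_that("epoch assembly is index-exact with the stated period layout", {
  pb <- streamsync:::.periodTable(0.5)
  expect_equal(pb$end - pb$start, c(0.5, 2.0, 1.9, 1.9, 2.0))
  expect_equal(pb$end[5], 7.8)
  for (rate in c(512, 64)) {
    counts <- streamsync:::.segmentCounts(rate, 0.5)
    expect_equal(unname(counts["encoding"]), floor(2 * rate))
    expect_equal(sum(counts[c("delay1", "delay2")]), floor(3.8 * rate))
  }
  ## epochs identical in length across different jitters
  n <- 512 * 40
  rec <- mkRecording(matrix(rnorm(2 * n), 2))
  ev <- mkEvents(2, onset0 = 8, gap = 13)
  ev$delay_s <- c(3.9, 4.1)
  ep1 <- epochRecording(rec, ev, baselineLength = 0.5)
  expect_equal(dim(epochData(ep1))[3], epochLen(512, 0.5))
  ## delay samples start 0.2 s after delay onset regardless of jitter
  d <- epochData(ep1)
  i0 <- round((ev$onset + 2.2) * 512) + 1
  idx <- periodSamples(ep1, "delay1")
  expect_equal(d[2, 1, idx[1]], samples(rec)[1, i0[2]])
  ## event too close to the recording edge errors with the trial number
  evBad <- mkEvents(1, onset0 = 0.1)
  expect_error(epochRecording(rec, evBad), "trial 1")
})

test_that("spike flagging hits injected transients and spares clean data", {
  set.seed(5)
  nS <- epochLen(512, 1.9)
  arr <- array(rnorm(20 * 2 * nS), dim = c(20, 2, nS))
  ## inject spikes into known (trial, channel) cells
  spikeShape <- 10 * sin(2 * pi * seq(0, 1, length.out = 36))
  hits <- rbind(c(3, 1), c(7, 2), c(15, 1))
  for (k in seq_len(nrow(hits)))
    arr[hits[k, 1], hits[k, 2], 1000:1035] <- spikeShape
  ep <- mkEpochSet(arr)
  flag <- flagSpikeEpochs(ep)
  expect_true(all(flag[hits]))
  expect_equal(sum(flag), nrow(hits))
  ## pure band-limited oscillation: nothing flagged
  t <- (seq_len(nS) - 1) / 512
  osc <- array(rep(sin(2 * pi * 9 * t), each = 8), dim = c(4, 2, nS))
  expect_equal(sum(flagSpikeEpochs(mkEpochSet(osc))), 0)
  ## all-zero epochs: zero variance guarded, not flagged
  expect_equal(sum(flagSpikeEpochs(mkEpochSet(array(0, c(4, 2, nS))))), 0)
})

test_that("simulator ground-truth spikes are detected at >= 90 %", {
  cfg <- simulationConfig(nTrialsPerCondition = 10, blockSize = 5,
                          channelsPerRegion = c(IPL = 2, VTC = 2, HIP = 1),
                          spikeRate = 30, lineNoiseAmplitude = 0)
  sim <- simulateSession(cfg, seed = 8)
  recB <- bipolarReference(sim$recording)
  ep <- epochRecording(recB, sim$events, baselineLength = 1.9)
  flag <- flagSpikeEpochs(ep)
  ## ground truth: a spike contaminates the two bipolar channels sharing
  ## its contact, in every trial whose epoch segments include its time
  chB <- channelTable(recB)
  truthCells <- matrix(FALSE, nrow(sim$events), nrow(chB))
  segs <- function(ev, i) rbind(
    c(ev$onset[i] - 1.9, ev$onset[i]),
    c(ev$onset[i], ev$onset[i] + 2),
    c(ev$onset[i] + 2.2, ev$onset[i] + 6.0),
    c(ev$onset[i] + 2 + ev$delay_s[i], ev$onset[i] + 4 + ev$delay_s[i]))
  spk <- sim$truth$spikes
  margin <- 0.1
  for (s in seq_len(nrow(spk))) {
    bip <- which(chB$shaft == spk$shaft[s] &
                   chB$contact_index %in% (spk$contact_index[s] - 1:0))
    for (i in seq_len(nrow(sim$events))) {
      sg <- segs(sim$events, i)
      inside <- any(spk$time[s] > sg[, 1] + margin &
                      spk$time[s] + 0.07 < sg[, 2] - margin)
      if (inside) truthCells[i, bip] <- TRUE
    }
  }
  expect_gt(sum(truthCells), 5)   # scenario actually exercises spikes
  sens <- sum(flag & truthCells) / sum(truthCells)
  expect_gte(sens, 0.9)
})

test_that("incorrect-response exclusion is trial-level and counted", {
  nS <- epochLen(512, 1.9)
  ep <- mkEpochSet(array(rnorm(8 * 2 * nS), dim = c(8, 2, nS)),
                   condition = factor(rep(c("same", "different"), each = 4),
                                      levels = c("same", "different")))
  ev <- mkEvents(8, condition = rep(c("same", "different"), each = 4))
  expect_equal(sum(excludeIncorrect(ep, ev)), 0)
  ev$correct_position[c(2, 5)] <- FALSE
  ev$correct_identity[7] <- FALSE        # different-condition trial
  mask <- excludeIncorrect(ep, ev)
  expect_equal(which(rowSums(mask) > 0), c(2, 5, 7))
  expect_true(all(mask[2, ]))            # all channels of the trial
  ep2 <- markExcluded(ep, mask, "incorrect_position")
  expect_equal(sum(exclusionMask(ep2)), 3 * 2)
  expect_equal(unique(ep2@reason[mask]), "incorrect_position")
})
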