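test_that("whitened envelopes have session mean 100 and flat-tone shape", {
  t <- (0:(512 * 60 - 1)) / 512
  rec <- mkRecording(matrix(20 * sin(2 * pi * 10.5 * t), 1))
  envs <- filterHilbertEnvelope(rec, 8, 13)
  v <- envelopeValues(envs)
  ## every band's session mean is exactly 100 by construction
  expect_equal(apply(v, c(1, 2), mean), matrix(100, 5, 1),
               tolerance = 1e-9, ignore_attr = TRUE)
  ## constant-amplitude tone: the containing band's envelope stays ~100
  b10 <- which(envs@bands == 10)
  mid <- 500:3300
  expect_lt(stats::sd(v[b10, 1, mid]), 2)
  expect_equal(mean(v[b10, 1, mid]), 100, tolerance = 1)
})

test_that("a doubled-amplitude half-session whitens to ~66.7 vs ~133.3", {
  n <- 512 * 60
  t <- (seq_len(n) - 1) / 512
  amp <- rep(c(1, 2), each = n / 2)
  rec <- mkRecording(matrix(amp * sin(2 * pi * 10 * t), 1))
  envs <- filterHilbertEnvelope(rec, 10, 11)
  v <- envelopeValues(envs)[1, 1, ]
  m <- length(v)
  ## interior of each half (edges carry filter transients)
  h1 <- mean(v[round(m * 0.1):round(m * 0.4)])
  h2 <- mean(v[round(m * 0.6):round(m * 0.9)])
  expect_equal(h1, 200 / 3, tolerance = 1)
  expect_equal(h2, 400 / 3, tolerance = 1)
})

test_that("band aggregation averages bins and baseline-corrects epochs", {
  set.seed(3)
  n <- 512 * 50
  rec <- mkRecording(matrix(rnorm(2 * n), 2), channels = mkChannels(2))
  envs <- filterHilbertEnvelope(rec, 8, 13)
  ev <- mkEvents(3, onset0 = 6, gap = 13)
  ## identical envelopes across the band -> aggregate equals any member
  envsSame <- envs
  for (k in 2:5) envsSame@values[k, , ] <- envsSame@values[1, , ]
  esSame <- aggregateBand(envsSame, "alpha", ev, baselineCorrect = FALSE)
  one <- aggregateBand(envsSame, 8L, ev, baselineCorrect = FALSE)
  expect_equal(envelopeValues(esSame), envelopeValues(one),
               tolerance = 1e-12)
  ## after baseline subtraction the [-0.5, 0) mean is 0 per trial/channel
  es <- aggregateBand(envs, "alpha", ev)
  bIdx <- streamsync:::.periodIdx(64, 0.5, "baseline")
  bMeans <- apply(envelopeValues(es)[, , bIdx, drop = FALSE], c(1, 2), mean)
  expect_equal(bMeans, matrix(0, 3, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(aggregateBand(envs, "theta", ev), "missing 1 Hz band")
})

test_that("active-channel detection finds true effects, spares nulls", {
  set.seed(7)
  nS <- epochLen(64, 0.5)
  postIdx <- (streamsync:::.periodIdx(64, 0.5, "baseline")[32] + 1):nS
  dIdx <- c(streamsync:::.periodIdx(64, 0.5, "delay1"),
            streamsync:::.periodIdx(64, 0.5, "delay2"))
  nT <- 40
  ## channel 1: +50 percentage-point step during the delay; channel 2 null
  mk <- function(effect) {
    arr <- array(100 + rnorm(nT * 2 * nS, sd = 10), dim = c(nT, 2, nS))
    if (effect) arr[, 1, dIdx] <- arr[, 1, dIdx] + 50
    arr
  }
  env <- mkEnvelopeSet(mk(TRUE),
                       condition = factor(rep("same", nT),
                                          levels = c("same", "different")))
  rep1 <- detectActiveChannels(env, "same")
  expect_true(rep1$report$active[1])
  expect_false(rep1$report$active[2])
  ## significant samples fall in the delay periods
  sigT <- which(rep1$sigMask[1, ])
  expect_true(all(sigT %in% (dIdx - 32)))
  ## constant envelope: all-zero differences -> p = 1 -> inactive
  envC <- mkEnvelopeSet(array(100, c(nT, 2, nS)),
                        condition = factor(rep("same", nT),
                                           levels = c("same", "different")))
  repC <- detectActiveChannels(envC, "same")
  expect_false(any(repC$report$active))
  ## too few trials: skipped with a warning
  envF <- mkEnvelopeSet(mk(TRUE)[1:4, 1, , drop = FALSE],
                        condition = factor(rep("same", 4),
                                           levels = c("same", "different")),
                        channels = mkChannels(1))
  expect_warning(detectActiveChannels(envF, "same"), "usable trial")
})

test_that("six-sample max-p smoothing only removes significant points", {
  set.seed(11)
  nS <- epochLen(64, 0.5)
  nT <- 30
  dIdx <- streamsync:::.periodIdx(64, 0.5, "delay1")
  arr <- array(100 + rnorm(nT * 1 * nS, sd = 10), dim = c(nT, 1, nS))
  arr[, 1, dIdx] <- arr[, 1, dIdx] + 30
  env <- mkEnvelopeSet(arr, condition = factor(rep("same", nT),
                                               levels = c("same", "different")))
  smoothed <- detectActiveChannels(env, "same", windowSamples = 6)
  raw <- detectActiveChannels(env, "same", windowSamples = 1)
  expect_true(all(which(smoothed$sigMask) %in% which(raw$sigMask)))
  expect_gte(sum(raw$sigMask), sum(smoothed$sigMask))
})

test_that("task-period power means keep the expected bookkeeping", {
  nS <- epochLen(64, 0.5)
  nT <- 8
  arr <- array(0, c(nT, 2, nS))
  for (p in streamsync:::PERIODS) {
    idx <- streamsync:::.periodIdx(64, 0.5, p)
    arr[, , idx] <- match(p, streamsync:::PERIODS) * 10
  }
  env <- mkEnvelopeSet(arr)
  tab <- averageTaskPeriods(env, patient = "P9")
  expect_equal(nrow(tab), 2 * 2 * 5)    # channels x conditions x periods
  expect_setequal(unique(tab$period), streamsync:::PERIODS)
  expect_equal(tab$mean_power[tab$period == "delay2"][1], 40)
  expect_equal(unique(tab$patient), "P9")
  ## active-channel restriction via reports
  fakeReport <- structure(list(report = data.frame(
    channel = env@channels$name, active = c(TRUE, FALSE))),
    class = "ActiveChannelReport")
  tab2 <- averageTaskPeriods(env, list(fakeReport))
  expect_equal(unique(tab2$channel), env@channels$name[1])
})
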