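test_that("multitaper spectra peak at the driving frequency", {
  nS <- epochLen(512, 1.9)
  t <- (seq_len(nS) - 1) / 512
  mk <- function(f) {
    arr <- array(0, c(3, 1, nS))
    for (i in 1:3) arr[i, 1, ] <- sin(2 * pi * f * t + i)
    mkEpochSet(arr, condition = factor(rep("same", 3),
                                       levels = c("same", "different")))
  }
  sp5 <- multitaperSpectra(mk(5), "delay1")
  mag <- Mod(spectraCoefficients(sp5)[1, 1, 1, ])
  expect_equal(spectraFrequencies(sp5)[which.max(mag)], 5)
  ## zero signal -> all-zero coefficients
  spZ <- multitaperSpectra(mkEpochSet(array(0, c(3, 1, nS)),
    condition = factor(rep("same", 3), levels = c("same", "different"))),
    "encoding")
  expect_true(all(Mod(spectraCoefficients(spZ)) == 0))
  ## 4 + 12 Hz mixture -> two distinct peaks
  arr <- array(0, c(2, 1, nS))
  arr[1, 1, ] <- arr[2, 1, ] <- sin(2 * pi * 4 * t) + sin(2 * pi * 12 * t)
  spM <- multitaperSpectra(mkEpochSet(arr,
    condition = factor(rep("same", 2), levels = c("same", "different"))),
    "delay2")
  m <- Mod(spectraCoefficients(spM)[1, 1, 1, ])
  f <- spectraFrequencies(spM)
  expect_setequal(f[order(m, decreasing = TRUE)[1:2]], c(4, 12))
  ## recall window is the first 0.5 s of the period
  spR <- multitaperSpectra(mk(5), "recall")
  expect_equal(spR@windowLength, 0.5)
})

test_that("PLV obeys its algebraic identities", {
  set.seed(13)
  nT <- 50; nF <- 19
  phA <- matrix(runif(nT * nF, -pi, pi), nT)
  ## constant phase offset -> PLV = 1 everywhere
  sp <- mkSpectraFromPhases(list(phA, phA + 0.7))
  expect_equal(computePLV(sp, 1, 2)$plv, rep(1, nF), tolerance = 1e-12)
  ## self-PLV = 1
  expect_equal(computePLV(sp, 1, 1)$plv, rep(1, nF), tolerance = 1e-12)
  ## two trials with phase differences 0 and pi cancel exactly
  sp0 <- mkSpectraFromPhases(list(matrix(0, 2, nF),
                                  matrix(rep(c(0, pi), nF), 2)))
  expect_equal(computePLV(sp0, 1, 2)$plv, rep(0, nF), tolerance = 1e-12)
  ## invariance under a fixed unit-modulus factor on one channel
  spShift <- sp
  spShift@coefficients[, , 2, ] <- spShift@coefficients[, , 2, ] *
    exp(1i * 1.234)
  expect_equal(computePLV(spShift, 1, 2)$plv, computePLV(sp, 1, 2)$plv,
               tolerance = 1e-12)
  ## magnitudes do not matter, only phases
  spMag <- sp
  spMag@coefficients[, , 1, ] <- spMag@coefficients[, , 1, ] *
    matrix(runif(nT * nF, 0.1, 9), nT)
  expect_equal(computePLV(spMag, 1, 2)$plv, computePLV(sp, 1, 2)$plv,
               tolerance = 1e-12)
})

test_that("PLV formula equals the explicit phase-difference oracle", {
  set.seed(17)
  nT <- 64; nF <- 19
  phA <- matrix(runif(nT * nF, -pi, pi), nT)
  phB <- matrix(runif(nT * nF, -pi, pi), nT)
  sp <- mkSpectraFromPhases(list(phA, phB))
  oracle <- sapply(seq_len(nF), function(f)
    Mod(mean(exp(1i * (phA[, f] - phB[, f])))))
  expect_equal(computePLV(sp, 1, 2)$plv, oracle, tolerance = 1e-12)
})

test_that("permutation test returns exact-null emptiness and detects coupling", {
  set.seed(19)
  nS <- epochLen(512, 1.9)
  nT <- 40
  ## exact null: task period data copied from the baseline segment
  arr <- array(rnorm(nT * 2 * nS), c(nT, 2, nS))
  bIdx <- periodSamples(mkEpochSet(arr), "baseline")
  d1Idx <- periodSamples(mkEpochSet(arr), "delay1")
  arr[, , d1Idx[1:length(bIdx)]] <- arr[, , bIdx]
  ep <- mkEpochSet(arr)
  spB <- multitaperSpectra(ep, "baseline")
  spT <- multitaperSpectra(ep, "delay1")
  tst <- permutationPLVTest(spT, spB, 1, 2, nPerm = 100, seed = 2)
  expect_false(tst$significant)
  expect_equal(sum(tst$mask), 0)
  expect_error(permutationPLVTest(spT, spB, 1, 2, nPerm = 10), ">= 20")
  ## injected 4 Hz phase coupling in the task period only
  t <- (seq_len(nS) - 1) / 512
  arr2 <- array(rnorm(nT * 2 * nS, sd = 0.3), c(nT, 2, nS))
  for (i in seq_len(nT)) {
    phi <- runif(1, 0, 2 * pi)
    dphi <- streamsync:::rvonmises(1, 0, 4)
    arr2[i, 1, d1Idx] <- arr2[i, 1, d1Idx] +
      cos(2 * pi * 4 * t[d1Idx] + phi)
    arr2[i, 2, d1Idx] <- arr2[i, 2, d1Idx] +
      cos(2 * pi * 4 * t[d1Idx] + phi + dphi)
  }
  ep2 <- mkEpochSet(arr2)
  tst2 <- permutationPLVTest(multitaperSpectra(ep2, "delay1"),
                             multitaperSpectra(ep2, "baseline"),
                             1, 2, nPerm = 200, seed = 3)
  expect_true(tst2$significant)
  expect_true(tst2$mask[which(tst2$frequency == 4)])
})

test_that("Sig.P.Ratio binomial selection flags enriched bins only", {
  ## all bins at ratio 0.10, one bin at 0.60, 100 pairs
  masks <- matrix(FALSE, 100, 19)
  for (f in 1:19) masks[1:10, f] <- TRUE
  masks[11:60, 5] <- TRUE                 # bin 6 Hz -> ratio 0.60
  sr <- sigPairRatio(masks)
  expect_equal(sr$median_ratio, 0.10)
  expect_true(sr$table$selected[5])
  expect_equal(sum(sr$table$selected), 1)
  expect_equal(sr$ranges, data.frame(f_lo = 6, f_hi = 6))
  ## exact binomial p-value cross-check for the enriched bin
  expect_equal(sr$table$p[5],
               stats::binom.test(60, 100, 0.10,
                                 alternative = "greater")$p.value)
  ## uniform ratios -> nothing selected
  srU <- sigPairRatio(matrix(rep(c(TRUE, FALSE), c(3, 7)), 10, 19))
  expect_false(any(srU$table$selected))
  expect_error(sigPairRatio(matrix(FALSE, 0, 19)), "no pairs")
})

test_that("period-averaged PLV tables aggregate selected ranges", {
  tab <- expand.grid(patient = "P1", pair_id = c("a~b", "a~c"),
                     period = c("baseline", "delay1"),
                     condition = c("same", "different"),
                     frequency = 2:20, stringsAsFactors = FALSE)
  tab$plv <- tab$frequency / 20
  out <- averagePLVPeriods(tab, data.frame(f_lo = 3, f_hi = 5))
  expect_equal(nrow(out), 2 * 2 * 2)
  expect_equal(unique(out$mean_plv), 4 / 20)
  single <- averagePLVPeriods(tab, data.frame(f_lo = 7, f_hi = 7))
  expect_equal(unique(single$mean_plv), 7 / 20)
  expect_error(averagePLVPeriods(tab, data.frame()[0, ]), "no selected")
})
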