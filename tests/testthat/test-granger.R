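test_that("40 Hz resampling preserves layout and low-frequency content", {
  counts <- streamsync:::.segmentCounts(40, 1.9)
  expect_equal(unname(counts["delay1"]), 76)     # 1.9 s x 40 Hz
  n <- 512 * 40
  t <- (seq_len(n) - 1) / 512
  ch <- rbind(mkChannels(1, shaft = "A", region = "IPL"),
              mkChannels(1, shaft = "B", region = "VTC"))
  ch$name <- c("a", "b")
  rec <- mkRecording(rbind(sin(2 * pi * 10 * t), 0 * t), channels = ch)
  ev <- mkEvents(2, onset0 = 8, gap = 13)
  ep40 <- downsampleForGC(rec, ev)
  expect_equal(samplingRate(ep40), 40)
  expect_equal(dim(epochData(ep40))[3], sum(counts))
  ## 10 Hz tone survives with < 1 % amplitude error
  seg <- epochData(ep40)[1, 1, periodSamples(ep40, "delay1")]
  expect_lt(abs(sqrt(2 * mean(seg^2)) - 1), 0.01)
  ## zero channel stays zero
  expect_equal(max(abs(epochData(ep40)[, 2, ])), 0)
})

test_that("CSD is Hermitian, self-consistent and separates channels", {
  set.seed(23)
  nTr <- 500
  ep <- mkEpochs40(nTr, function(i) matrix(rnorm(2 * 388), 2))
  csd <- computeCSD(ep, 1, 2, "delay1")
  expect_equal(csd$nTrials, nTr)
  ## Hermitian with real non-negative diagonal
  expect_equal(csd$S[1, 2, ], Conj(csd$S[2, 1, ]), tolerance = 1e-12)
  expect_true(all(Re(csd$S[1, 1, ]) >= 0) && all(abs(Im(csd$S[1, 1, ])) < 1e-14))
  ## independent channels: coherence small everywhere at 500 trials
  coh <- Mod(csd$S[1, 2, ]) / sqrt(Re(csd$S[1, 1, ]) * Re(csd$S[2, 2, ]))
  expect_lt(max(coh), 0.1)
  ## identical channels: coherence exactly 1
  epSame <- mkEpochs40(50, function(i) {
    x <- rnorm(388); rbind(x, x)
  })
  csdS <- computeCSD(epSame, 1, 2, "delay1")
  cohS <- Mod(csdS$S[1, 2, ]) / sqrt(Re(csdS$S[1, 1, ]) * Re(csdS$S[2, 2, ]))
  expect_equal(cohS, rep(1, length(cohS)), tolerance = 1e-9)
  ## recall period refused; too few trials refused
  expect_error(computeCSD(ep, 1, 2, "recall"), "recall")
  expect_error(computeCSD(mkEpochs40(5, function(i)
    matrix(rnorm(2 * 388), 2)), 1, 2, "delay1"), "usable trial")
})

test_that("Wilson factorization reproduces identity and VAR spectra", {
  freqs <- seq(0, 20, by = 0.05)
  nF <- length(freqs)
  ## S = I -> H = I, Sigma = I
  csdI <- structure(list(S = array(rep(diag(2), nF) + 0i, c(2, 2, nF)),
                         frequency = freqs, nTrials = 100L, nTapers = 2L,
                         pair = c("a", "b"), period = "delay1",
                         condition = "both"), class = "CSDMatrix")
  fI <- wilsonFactorize(csdI)
  expect_true(fI$converged)
  expect_lt(fI$residual, 1e-10)
  expect_equal(fI$Sigma, diag(2), tolerance = 1e-8)
  expect_lt(max(Mod(fI$H - array(rep(diag(2), nF), c(2, 2, nF)))), 1e-8)
  ## analytic VAR(1) spectrum: recovered Sigma within 1e-3 elementwise
  A <- list(matrix(c(0.5, 0.4, 0.0, 0.3), 2, 2))
  Sigma <- matrix(c(1, 0.2, 0.2, 0.8), 2, 2)
  par <- parametricVARGC(A, Sigma, freqs, 40)
  csdV <- structure(list(S = par$S, frequency = freqs, nTrials = 100L,
                         nTapers = 2L, pair = c("x", "y"),
                         period = "delay1", condition = "both"),
                    class = "CSDMatrix")
  fV <- wilsonFactorize(csdV)
  expect_true(fV$converged)
  expect_lt(fV$residual, 1e-6)
  expect_equal(fV$Sigma, Sigma, tolerance = 1e-3)
  ## reconstruction property on a further random stable VAR(2)
  set.seed(29)
  A2 <- list(matrix(c(0.4, 0.2, -0.1, 0.3), 2, 2),
             matrix(c(-0.2, 0.1, 0.05, -0.25), 2, 2))
  S2 <- parametricVARGC(A2, diag(c(1, 1.5)), freqs, 40)$S
  csd2 <- structure(list(S = S2, frequency = freqs, nTrials = 100L,
                         nTapers = 2L, pair = c("x", "y"),
                         period = "delay1", condition = "both"),
                    class = "CSDMatrix")
  expect_lt(wilsonFactorize(csd2)$residual, 1e-6)
})

test_that("nonparametric GC matches the parametric oracle and symmetry", {
  freqs <- seq(0, 20, by = 0.05)
  ## unidirectional VAR(2) x -> y with an oscillatory resonance
  A <- list(matrix(c(0.6, 0.5, 0, 0.7), 2, 2),
            matrix(c(-0.5, -0.2, 0, -0.6), 2, 2))
  Sigma <- diag(c(1, 0.7))
  par <- parametricVARGC(A, Sigma, freqs, 40)
  csd <- structure(list(S = par$S, frequency = freqs, nTrials = 100L,
                        nTapers = 2L, pair = c("x", "y"),
                        period = "delay1", condition = "both"),
                   class = "CSDMatrix")
  gc <- spectralGC(wilsonFactorize(csd))
  expect_true(all(gc$gc_xy >= 0) && all(gc$gc_yx >= 0))
  expect_equal(gc$net, gc$gc_yx - gc$gc_xy)
  k <- which.max(par$gc_xy)
  expect_lt(abs(gc$gc_xy[k] - par$gc_xy[k]) / par$gc_xy[k], 0.10)
  expect_lt(max(gc$gc_yx), 0.10 * par$gc_xy[k])
  ## swapping channel order swaps the directed spectra exactly
  csdSw <- csd
  csdSw$S <- csd$S[2:1, 2:1, ]
  gcSw <- spectralGC(wilsonFactorize(csdSw))
  expect_equal(gcSw$gc_xy, gc$gc_yx, tolerance = 1e-7)
  expect_equal(gcSw$gc_yx, gc$gc_xy, tolerance = 1e-7)
  ## independent channels from Monte-Carlo CSD: GC < 0.01 at 500 trials
  set.seed(31)
  ep <- mkEpochs40(500, function(i) matrix(rnorm(2 * 388), 2))
  gcI <- spectralGC(wilsonFactorize(computeCSD(ep, 1, 2, "delay1")))
  expect_lt(max(gcI$gc_xy, gcI$gc_yx), 0.01)
})

test_that("peak-band selection finds extrema and handles flat spectra", {
  f <- seq(1, 20, by = 0.05)
  ## two opposite-sign peaks at 3 and 10 Hz
  net <- 0.3 * exp(-(f - 3)^2 / 0.5) - 0.25 * exp(-(f - 10)^2 / 0.8)
  sel <- selectPeakBand(net, f)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$f_peak, c(3, 10), tolerance = 0.1)
  expect_equal(sel$sign, c(1, -1))
  expect_equal(sel$f_lo, sel$f_peak - 1)
  expect_equal(sel$f_hi, sel$f_peak + 1)
  ## flat spectrum -> empty selection
  expect_equal(nrow(selectPeakBand(rep(0, length(f)), f)), 0)
  expect_equal(nrow(selectPeakBand(rnorm(length(f), sd = 1e-5), f)), 0)
  ## matrix input averages rows
  m <- rbind(net + 0.01, net - 0.01)
  expect_equal(selectPeakBand(m, f)$f_peak, sel$f_peak)
})

test_that("period-averaged net GC aggregates ranges and bookkeeping", {
  tab <- expand.grid(patient = "P1", pair_id = c("p~q", "p~r"),
                     period = c("baseline", "encoding", "delay1", "delay2"),
                     condition = c("same", "different"),
                     frequency = seq(1, 20, 0.5), stringsAsFactors = FALSE)
  tab$net <- ifelse(tab$frequency >= 3 & tab$frequency <= 5, 0.2, 0)
  out <- averageNetGCPeriods(tab, data.frame(f_lo = 3, f_hi = 5))
  expect_equal(nrow(out), 2 * 4 * 2)     # pairs x periods x conditions
  expect_equal(unique(out$mean_net_gc), 0.2)
  expect_false("recall" %in% out$period)
  single <- averageNetGCPeriods(tab, data.frame(f_lo = 4, f_hi = 4))
  expect_equal(unique(single$mean_net_gc), 0.2)
})
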