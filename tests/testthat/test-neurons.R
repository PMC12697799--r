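test_that("homogeneous Poisson trains behave like a Poisson process", {
  expect_error(simulatePoisson(-1, 10), "rate")
  expect_identical(length(spikeTimes(simulatePoisson(0, 10, seed = 1))), 0L)
  # count within 3 sigma of rate * duration
  tr <- simulatePoisson(20, 300, seed = 5)
  expect_lt(abs(length(spikeTimes(tr)) - 6000), 3 * sqrt(6000))
  expect_identical(spikeTimes(simulatePoisson(7, 30, seed = 2)),
                   spikeTimes(simulatePoisson(7, 30, seed = 2)))
  expect_false(is.unsorted(spikeTimes(tr)))
})

test_that("zero-gain LNP units reduce to the Poisson baseline", {
  sp <- fixtureStimulus()
  spec <- encoderSpec(gain = 0, baselineRate = 8, bf = 16000, seed = 3)
  tr <- simulateLNP(spec, sp)
  # expected count 8 sp/s * 20 s = 160; allow 3 sigma
  expect_lt(abs(length(spikeTimes(tr)) - 160), 3 * sqrt(160))
})

test_that("the realized LNP rate matches the analytic rate integral", {
  # constant ridge at bf: rate(t) is constant after the latency, and its
  # integral is computable in closed form from the same Gaussian kernel
  ax <- logFrequencyAxis()
  ctr <- frequencyCenters(ax)
  bf <- ctr[23]
  nt <- 4000L                                     # 20 s at 5 ms
  prof <- exp(-(log2(ctr) - log2(bf))^2 / (2 * 0.15^2))
  sp <- new("Spectrogram", energy = matrix(prof, nrow = length(ctr),
                                           ncol = nt), dt = 0.005, axis = ax)
  spec <- encoderSpec(bf = bf, gain = 60, baselineRate = 2,
                      bandwidth = 0.5, latency = 0.015, jitter = 0,
                      refractory = 0, seed = 11)
  # oracle: drive = sum over channels of the unit-sum frequency kernel
  # times the static profile; temporal convolution of a constant is the
  # constant; the latency zeroes the first bins
  wf <- dnorm(log2(ctr), log2(bf), 0.5)
  wf <- wf / sum(wf)
  drive <- sum(wf * prof)
  lagBins <- round(0.015 / 0.005)
  expected <- 2 * 20 + 60 * drive * (nt - lagBins) * 0.005
  tr <- simulateLNP(spec, sp)
  expect_lt(abs(length(spikeTimes(tr)) - expected), 3 * sqrt(expected))
})

test_that("LNP spiking tracks the stimulus at the encoded latency", {
  sw <- generateRDS(duration = 20, seed = 21, trajectoryDt = 0.001)
  sp <- renderSpectrogram(sw, dt = 0.001)
  spec <- encoderSpec(bf = 16000, gain = 150, baselineRate = 0,
                      bandwidth = 0.3, kernelWidth = 0.002,
                      latency = 0.015, jitter = 0, refractory = 0,
                      seed = 13)
  tr <- simulateLNP(spec, sp)
  # cross-correlate the zero-latency drive with the binned spike train:
  # the peak must sit at the encoded 15 ms latency (1 ms resolution)
  spec0 <- spec; spec0@latency <- 0
  rate0 <- ncrtools:::lnpRate(spec0, sp)
  counts <- tabulate(pmin(floor(spikeTimes(tr) / 0.001) + 1L, 20000L),
                     nbins = 20000L)
  lags <- 0:40
  cc <- vapply(lags, function(L) {
    n <- length(rate0) - L
    cor(rate0[seq_len(n)], counts[seq_len(n) + L])
  }, numeric(1))
  bestMs <- lags[which.max(cc)]
  expect_lte(abs(bestMs - 15), 1)
})

test_that("rate conservation holds across seeds without jitter/refractory", {
  sp <- fixtureStimulus()
  total <- 0
  for (s in 1:10) {
    spec <- encoderSpec(bf = 16000, gain = 40, baselineRate = 3,
                        jitter = 0, refractory = 0, seed = 100 + s)
    total <- total + length(spikeTimes(simulateLNP(spec, sp)))
  }
  rate <- ncrtools:::lnpRate(encoderSpec(bf = 16000, gain = 40,
                                         baselineRate = 3, jitter = 0,
                                         refractory = 0, seed = 1), sp)
  expected <- 10 * sum(rate) * sp@dt
  expect_lt(abs(total - expected), 4 * sqrt(expected))
})

test_that("LNP units reject out-of-band best frequencies", {
  sp <- fixtureStimulus()
  expect_error(simulateLNP(encoderSpec(bf = 500, seed = 1), sp),
               "outside the stimulus band")
})

test_that("the refractory period prunes close spikes", {
  sp <- fixtureStimulus()
  spec <- encoderSpec(bf = 16000, gain = 150, baselineRate = 10,
                      jitter = 0, refractory = 0.005, seed = 17)
  tr <- simulateLNP(spec, sp)
  expect_true(all(diff(spikeTimes(tr)) >= 0.005 - 1e-12))
})

test_that("merging units preserves and sums spikes", {
  a <- mkTrain(c(0.1, 0.5), 1, "a")
  b <- mkTrain(c(0.2, 0.7), 1, "b")
  m <- mergeUnits(list(a, b))
  expect_identical(spikeTimes(m), c(0.1, 0.2, 0.5, 0.7))
  expect_identical(length(spikeTimes(mergeUnits(list(a)))), 2L)
  expect_identical(spikeTimes(mergeUnits(list(a))), spikeTimes(a))
  expect_error(mergeUnits(list(a, mkTrain(0.1, 2))), "duration")
})

test_that("mean evoked rate is count over duration and additive", {
  tr <- mkTrain(seq(0.5, 299.5, by = 1), 300)
  expect_equal(meanEvokedRate(tr), 1)
  expect_equal(meanEvokedRate(mkTrain(numeric(0), 10)), 0)
  a <- mkTrain(c(0.1, 0.5), 1, "a")
  b <- mkTrain(c(0.2, 0.7, 0.9), 1, "b")
  expect_equal(meanEvokedRate(mergeUnits(list(a, b))),
               meanEvokedRate(a) + meanEvokedRate(b))
})
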