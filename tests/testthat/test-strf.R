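# a crafted STRF for feature tests
mkStrf <- function(smoothed, maskTrue, axis = logFrequencyAxis()) {
  new("STRF", psth = pmax(smoothed, 0), smoothed = smoothed,
      binDt = 1e-3, axis = axis, baselineMean = 0, baselineSd = 1,
      mask = maskTrue, sdThreshold = 6, features = list())
}

test_that("5x5 smoothing conserves the grid sum within 1%", {
  set.seed(21)
  m <- matrix(rexp(45 * 240), 45, 240)
  sm <- ncrtools:::smooth5x5(m)
  expect_lt(abs(sum(sm) - sum(m)) / sum(m), 0.01)
  expect_identical(dim(sm), dim(m))
})

test_that("a zero-spike train yields an all-zero STRF", {
  sch <- generateToneSchedule(seed = 41)
  tr <- mkTrain(numeric(0), duration(sch))
  strf <- buildSTRF(tr, sch)
  expect_true(all(strf@psth == 0))
  expect_false(any(strf@mask))
  expect_equal(strfFeatures(strf)$bandwidthOct, 0)
  expect_false(strfFeatures(strf)$bfReliable)
})

test_that("bandwidth sums the octave extents of disjoint peaks", {
  ax <- logFrequencyAxis()
  spacing <- (log2(90000) - log2(2000)) / 44
  sm <- matrix(0, 45, 100)
  mask <- matrix(FALSE, 45, 100)
  # two disjoint significant regions: 9 and 4 channels wide
  mask[5:13, 20:40] <- TRUE
  mask[30:33, 20:40] <- TRUE
  sm[mask] <- 50
  sm[8, 25] <- 80                           # global peak in region 1
  strf <- mkStrf(sm, mask, ax)
  ft <- extractSTRFFeatures(strf)
  expect_equal(ft$bandwidthOct, (9 + 4) * spacing)
  expect_equal(ft$bestFrequencyHz, frequencyCenters(ax)[8])
  expect_equal(ft$maxRate, 80)
  expect_equal(ft$firstSpikeLatencyMs, 19)  # first significant bin at bf
  expect_equal(ft$responseDurationMs, 21)
})

test_that("a flat grid has no significant tuning", {
  strf <- mkStrf(matrix(1, 45, 100), matrix(FALSE, 45, 100))
  ft <- extractSTRFFeatures(strf)
  expect_equal(ft$bandwidthOct, 0)
  expect_false(ft$bfReliable)
  expect_true(is.na(ft$firstSpikeLatencyMs))
})

test_that("tuning partition means follow the significant range", {
  ax <- logFrequencyAxis()
  mask <- matrix(FALSE, 45, 50)
  mask[20:30, 10:20] <- TRUE
  strf <- mkStrf(matrix(1, 45, 50), mask, ax)
  prof <- c(rep(0.2, 19), rep(0.6, 11), rep(0.1, 15))
  pt <- partitionByTuning(prof, strf)
  expect_equal(pt$below, 0.2)
  expect_equal(pt$within, 0.6)
  expect_equal(pt$above, 0.1)
  expect_identical(unname(pt$n), c(19L, 11L, 15L))
  # uniform profile: all three means equal
  pu <- partitionByTuning(rep(0.5, 45), strf)
  expect_equal(pu$below, pu$within)
  expect_equal(pu$within, pu$above)
  # mask covering the whole axis leaves below/above empty-flagged
  fullMask <- matrix(TRUE, 45, 50)
  pf <- partitionByTuning(prof, mkStrf(matrix(1, 45, 50), fullMask, ax))
  expect_true(is.na(pf$below))
  expect_true(is.na(pf$above))
  expect_error(partitionByTuning(prof,
                                 mkStrf(matrix(1, 45, 50),
                                        matrix(FALSE, 45, 50), ax)),
               "undefined")
})

test_that("best-frequency-centered profiles normalize and align", {
  ax <- logFrequencyAxis()
  ctr <- frequencyCenters(ax)
  prof <- dnorm(log2(ctr), log2(ctr[23]), 0.4)
  bp <- bfCenteredProfile(prof, ctr[23], ax)
  at0 <- which(abs(bp@offsets) < 1e-9)
  expect_equal(bp@values[at0], 1)
  expect_equal(max(bp@values, na.rm = TRUE), 1)
  # bf at the lowest channel: all negative offsets are missing
  bp1 <- bfCenteredProfile(prof, ctr[1], ax)
  expect_true(all(is.na(bp1@values[bp1@offsets < -1e-9])))
  # all-zero profile: sentinel (all NA)
  bp0 <- bfCenteredProfile(rep(0, 45), ctr[10], ax)
  expect_true(all(is.na(bp0@values)))
})

test_that("population averaging of BF profiles is missing-aware", {
  ax <- logFrequencyAxis()
  ctr <- frequencyCenters(ax)
  p1 <- bfCenteredProfile(dnorm(log2(ctr), log2(ctr[10]), 0.3), ctr[10], ax)
  p2 <- bfCenteredProfile(dnorm(log2(ctr), log2(ctr[35]), 0.3), ctr[35], ax)
  avg <- averageBFProfiles(list(p1, p2))
  at0 <- which(abs(avg@offsets) < 1e-9)
  expect_equal(avg@values[at0], 1)
  expect_equal(max(avg@values, na.rm = TRUE), 1)
  # offsets covered by a single profile equal that profile's value
  far <- which(avg@offsets > 2.9 & avg@offsets < 3.1)
  expect_equal(avg@values[far], p1@values[far])
})

test_that("an LNP unit's tuning is recovered from tone responses", {
  ax <- logFrequencyAxis()
  sch <- generateToneSchedule(ax, seed = 42)
  tone <- renderToneSpectrogram(sch, ax, dt = 0.001)
  bfTrue <- 16000
  # tone-evoked peak rates of well-driven units reach 150+ sp/s, well
  # above the 6-SD counting-noise criterion
  spec <- encoderSpec(bf = bfTrue, gain = 450, baselineRate = 2,
                      bandwidth = 0.4, latency = 0.012,
                      kernelWidth = 0.003, seed = 43)
  tr <- simulateLNP(spec, tone)
  strf <- buildSTRF(tr, sch)
  ft <- strfFeatures(strf)
  expect_true(ft$bfReliable)
  expect_lt(abs(log2(ft$bestFrequencyHz / bfTrue)), 0.25)
  expect_gt(ft$bandwidthOct, 0)
  expect_lt(abs(ft$firstSpikeLatencyMs - 12), 10)
})

test_that("the 6-SD rule rarely marks untuned Poisson units", {
  sch <- generateToneSchedule(seed = 44)
  hits <- 0L
  for (s in 1:10) {
    tr <- simulatePoisson(10, duration(sch), seed = 500 + s)
    strf <- buildSTRF(tr, sch)
    if (any(strf@mask)) hits <- hits + 1L
  }
  expect_lte(hits, 1L)
})
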