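# hand-built window sets give full control over the neighbor geometry
mkWindowSet <- function(vectors, stride = 0.1, length = 0.1,
                        codeKind = "rate") {
  n <- nrow(vectors)
  new("WindowSet", starts = (seq_len(n) - 1L) * stride, length = length,
      stride = stride, codeKind = codeKind, vectors = vectors,
      counts = matrix(0L, n, 1), unitIds = "u",
      duration = (n - 1) * stride + length, binDt = 5e-4)
}

test_that("an identical non-overlapping candidate ranks first at distance 0", {
  v <- rbind(c(1, 2), c(9, 9), c(1, 2), c(5, 5), c(7, 1), c(0, 4))
  w <- mkWindowSet(v)
  nb <- findNeighbors(w, k = 2, queryIdx = 1L)
  expect_identical(nb@neighbors[1, 1], 3L)
  expect_equal(nb@distances[1, 1], 0)
  expect_true(all(diff(nb@distances[1, ]) >= 0))
})

test_that("overlapping candidates are excluded", {
  # windows 100 ms long at 50 ms stride: neighbors of query 3 may not be
  # windows 2, 3 or 4
  v <- matrix(rnorm(40), 20, 2)
  w <- mkWindowSet(v, stride = 0.05)
  nb <- findNeighbors(w, k = 10, queryIdx = 3L)
  expect_false(any(nb@neighbors[1, ] %in% 2:4))
})

test_that("total ties resolve by seeded sampling, reproducibly", {
  v <- matrix(1, 30, 2)                  # all windows identical
  w <- mkWindowSet(v)
  n1 <- findNeighbors(w, k = 5, tieSeed = 7)
  n2 <- findNeighbors(w, k = 5, tieSeed = 7)
  expect_identical(n1@neighbors, n2@neighbors)
  n3 <- findNeighbors(w, k = 5, tieSeed = 8)
  expect_false(identical(n1@neighbors, n3@neighbors))
  expect_true(all(n1@distances == 0))
})

test_that("capacity violations raise an explicit error", {
  v <- matrix(rnorm(10), 5, 2)
  w <- mkWindowSet(v)
  expect_error(findNeighbors(w, k = 6), "capacity")
  expect_error(findNeighbors(w, k = 5, queryIdx = 3L), "capacity")
})

test_that("reconstruction averages the neighbor segments exactly", {
  ax <- logFrequencyAxis(4000, 16000, 5)
  # three constant 100 ms blocks with column profile v, 3v, 5v
  v <- c(1, 0, 2, 0, 1)
  A <- cbind(matrix(v, 5, 20), matrix(3 * v, 5, 20), matrix(5 * v, 5, 20))
  sp <- new("Spectrogram", energy = A, dt = 0.005, axis = ax)
  starts <- (0:20) * 0.01
  # query window 15 (start 0.14 s); k = 4 neighbors split between the
  # block-A window (start 0) and the block-B window (start 0.1)
  nb <- new("NeighborTable", queryIdx = 15L, candIdx = seq_along(starts),
            neighbors = matrix(c(1L, 1L, 11L, 11L), 1), k = 4L,
            distances = matrix(0, 1, 4), exclusionHalfwidth = 0.1,
            tieSeed = 1L, windowStarts = starts, windowLength = 0.1)
  dec <- reconstruct(nb, sp, lags = 0)
  cov <- which(dec@coverage > 0)
  expect_identical(cov, 29:48)           # query start 0.14 s, 20 columns
  expect_equal(dec@predicted[, cov], matrix(2 * v, 5, 20),
               tolerance = 1e-12)        # (A + B)/2 = (v + 3v)/2
  expect_true(all(is.na(dec@predicted[, -cov])))
  # all-identical neighbors reproduce their segment exactly
  nbA <- new("NeighborTable", queryIdx = 15L, candIdx = seq_along(starts),
             neighbors = matrix(rep(11L, 4), 1), k = 4L,
             distances = matrix(0, 1, 4), exclusionHalfwidth = 0.1,
             tieSeed = 1L, windowStarts = starts, windowLength = 0.1)
  decA <- reconstruct(nbA, sp, lags = 0)
  expect_equal(decA@predicted[, 29:48], matrix(3 * v, 5, 20),
               tolerance = 1e-12)
  expect_error(reconstruct(nb, sp, lags = numeric(0)), "lag")
})

test_that("a constant stimulus reconstructs constant under lag averaging", {
  ax <- logFrequencyAxis(4000, 16000, 5)
  sp <- new("Spectrogram", energy = matrix(1, 5, 200), dt = 0.005,
            axis = ax)
  tr <- simulatePoisson(20, 1, seed = 2)
  p <- fixtureParams(k = 10, evalStride = 0.05)
  prep <- ncrtools:::prepareNeighbors(tr, sp, "rate", p)
  dec <- reconstruct(prep$neighbors, sp, lags = c(-0.01, 0))
  cov <- dec@coverage > 0
  expect_true(all(abs(dec@predicted[, cov] - 1) < 1e-12))
})

test_that("scoring matches its closed-form cases", {
  ax <- logFrequencyAxis(2000, 90000, 45)
  set.seed(5)
  A <- matrix(runif(45 * 300), 45, 300)
  sp <- new("Spectrogram", energy = A, dt = 0.005, axis = ax)
  mkDec <- function(P) new("DecodedStimulus", predicted = P,
                           coverage = rep(1L, ncol(P)), lags = 0,
                           dt = 0.005, axis = ax)
  perfect <- score(sp, mkDec(A))
  expect_equal(perfect@corrSigned, 1)
  expect_equal(perfect@ncr, 0)
  # a negated prediction carries the same information: ncr = 0
  neg <- score(sp, mkDec(max(A) - A))
  expect_equal(neg@corrSigned, -1)
  expect_equal(neg@ncr, 0)
  expect_true(all(abs(neg@corrT + 1) < 1e-9))
  # independent noise over >= 1e4 pixels decodes nothing
  noise <- score(sp, mkDec(matrix(rnorm(45 * 300), 45, 300)))
  expect_lt(noise@ncr, -1.5)
  # constant prediction: no-information sentinel
  flat <- score(sp, mkDec(matrix(2, 45, 300)))
  expect_identical(flat@ncr, -Inf)
  expect_true(is.na(flat@corrSigned))
})

test_that("decoding is deterministic and self-pair invariant", {
  sp <- fixtureStimulus()
  tr <- simulatePoisson(12, duration(sp), seed = 4)
  p <- fixtureParams()
  r1 <- decode(tr, sp, "temporal", p)
  r2 <- decode(tr, sp, "temporal", p)
  expect_identical(r1@ncr, r2@ncr)
  expect_identical(r1@corrF, r2@corrF)
  # concatenating a unit with itself multiplies every distance by sqrt(2)
  # and must leave the decoding untouched, bit for bit
  rp <- decode(list(tr, tr), sp, "temporal", p)
  expect_identical(r1@ncr, rp@ncr)
  expect_identical(r1@corrT, rp@corrT)
  rr <- decode(tr, sp, "rate", p)
  rrp <- decode(list(tr, tr), sp, "rate", p)
  expect_identical(rr@ncr, rrp@ncr)
})

test_that("NCR is non-positive with |corr| = 10^ncr", {
  sp <- fixtureStimulus()
  for (s in 1:2) {
    tr <- simulatePoisson(10 * s, duration(sp), seed = 40 + s)
    res <- decode(tr, sp, "temporal", fixtureParams())
    expect_lte(res@ncr, 0)
    expect_equal(abs(res@corrSigned), 10^res@ncr)
    expect_true(all(abs(stats::na.omit(res@corrT)) <= 1 + 1e-9))
    expect_true(all(abs(stats::na.omit(res@corrF)) <= 1 + 1e-9))
  }
})

test_that("masked decoding restricts queries and candidates", {
  sp <- fixtureStimulus()
  tr <- simulatePoisson(10, duration(sp), seed = 6)
  p <- fixtureParams(k = 15)
  w <- makeWindows(tr, "temporal", length = p@windowLength,
                   stride = p@candidateStride)
  sil <- makeMask(w, "silence")
  res <- decode(tr, sp, "temporal", p, mask = sil)
  expect_identical(res@maskKind, "silence")
  expect_true(is.finite(res@ncr) || res@ncr == -Inf)
  # a silent unit under a silence mask is total-tie decoding yet runs
  quiet <- mkTrain(numeric(0), duration(sp), "q")
  wq <- makeWindows(quiet, "temporal", length = p@windowLength,
                    stride = p@candidateStride)
  resq <- decode(quiet, sp, "temporal", p, mask = makeMask(wq, "silence"))
  expect_lte(resq@ncr, 0)
  # masked pools below k raise a capacity error mentioning the remedy
  busy <- simulatePoisson(80, duration(sp), seed = 7)
  wb <- makeWindows(busy, "temporal", length = p@windowLength,
                    stride = p@candidateStride)
  silb <- makeMask(wb, "silence")
  expect_error(decode(busy, sp, "temporal", ncrParams(k = 5000),
                      mask = silb), "capacity|restriction")
})

test_that("lag scans recover ties to the smallest delay", {
  # constant stimulus: every delay reconstructs the same constant image,
  # the profile is flat (-Inf throughout) and the smallest delay wins
  ax <- logFrequencyAxis(4000, 16000, 5)
  sp <- new("Spectrogram", energy = matrix(1, 5, 400), dt = 0.005,
            axis = ax)
  tr <- simulatePoisson(15, duration(sp), seed = 10)
  p <- fixtureParams(k = 10)
  sl <- scanLags(tr, sp, "temporal", delays = c(0.02, 0, 0.01), params = p)
  expect_true(all(sl$table$ncr == sl$table$ncr[1]))
  expect_equal(sl$bestDelay, 0)
  expect_error(scanLags(tr, sp, "temporal", delays = numeric(0)),
               "non-empty")
})

test_that("window-size scans validate sizes and reproduce", {
  sp <- fixtureStimulus()
  tr <- simulatePoisson(15, duration(sp), seed = 8)
  p <- fixtureParams(k = 10)
  expect_error(scanWindowSizes(tr, sp, "rate", sizes = 30, params = p),
               "duration")
  out1 <- scanWindowSizes(tr, sp, "rate", sizes = c(0.05, 0.1),
                          params = p)
  out2 <- scanWindowSizes(tr, sp, "rate", sizes = c(0.05, 0.1),
                          params = p)
  expect_identical(out1, out2)
  expect_identical(nrow(out1), 2L)
})

test_that("null calibration validates inputs and records parameters", {
  sp <- fixtureStimulus()
  expect_error(calibrateNull(sp, nTrains = 0), "positive")
  expect_warning(
    cal <- calibrateNull(sp, nTrains = 4, params = fixtureParams(),
                         seed = 9),
    "unstable")
  expect_identical(nrow(cal@samples), 8L)        # both codes pooled
  expect_true(all(c("temporal", "rate") %in% cal@samples$code))
  expect_lte(threshold(cal), 0)
  expect_identical(cal@params$k, 20L)
})

test_that("NCR increases with the evoked drive of a tuned encoder", {
  # median NCR over seeds is non-decreasing across encoder gains spanning
  # no signal to a strong drive (mean rates up to ~30 sp/s)
  sp <- renderSpectrogram(generateRDS(duration = 60, seed = 2027),
                          dt = 0.005)
  p <- ncrParams(k = 50, keepPrediction = FALSE)
  med <- vapply(c(0, 50, 120, 250), function(g) {
    ncrs <- vapply(1:10, function(s) {
      e <- encoderSpec(bf = 16000, gain = g, baselineRate = 5,
                       bandwidth = 0.4, latency = 0.01, seed = 3000 + s)
      ncr(decode(simulateLNP(e, sp), sp, "temporal", p))
    }, numeric(1))
    stats::median(ncrs)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("NCR tracks mutual information for bivariate-normal surrogates", {
  # for jointly normal stimulus/prediction pixels with correlation rho,
  # MI = -log(1 - rho^2)/2; NCR = log10(rho) must increase with MI
  ax <- logFrequencyAxis(2000, 90000, 45)
  set.seed(77)
  n <- 45 * 400
  z1 <- rnorm(n); z2 <- rnorm(n)
  rhos <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ncrs <- vapply(rhos, function(rho) {
    a <- z1
    b <- rho * z1 + sqrt(1 - rho^2) * z2
    A <- matrix(a - min(a), 45)            # shift: energy must be >= 0
    sp <- new("Spectrogram", energy = A, dt = 0.005, axis = ax)
    dec <- new("DecodedStimulus", predicted = matrix(b, 45),
               coverage = rep(1L, 400), lags = 0, dt = 0.005, axis = ax)
    score(sp, dec)@ncr
  }, numeric(1))
  mi <- -0.5 * log(1 - rhos^2)
  expect_true(all(diff(mi) > 0))
  expect_true(all(diff(ncrs) > 0))
  expect_equal(ncrs, log10(rhos), tolerance = 0.05)
})
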