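test_that("binAndSmooth produces peak-normalized Hann bumps", {
  empty <- binAndSmooth(mkTrain(numeric(0), 0.2))
  expect_true(all(empty@values == 0))
  one <- binAndSmooth(mkTrain(0.05, 0.2))
  expect_equal(max(one@values), 1)
  expect_identical(which.max(one@values), 101L)    # bin holding t = 50 ms
  # two spikes separated by more than the taper support superpose exactly
  two <- binAndSmooth(mkTrain(c(0.03, 0.06), 0.2))
  w <- oracleHann()
  expected <- numeric(400)
  for (tb in c(61L, 121L))
    expected[tb + (-9:9)] <- expected[tb + (-9:9)] + w
  expect_equal(two@values, expected, tolerance = 1e-12)
})

test_that("binAndSmooth validates the taper discretization", {
  expect_error(binAndSmooth(mkTrain(0.1, 1), hannLen = 9.2e-3),
               "integer multiple")
  expect_error(binAndSmooth(mkTrain(0.1, 1), hannLen = 9.5e-3), "odd")
})

test_that("window counts and vector layout follow the stride arithmetic", {
  tr <- mkTrain(c(0.005, 0.006, 0.007, 0.5), 1)
  w <- makeWindows(tr, "rate", length = 0.1, stride = 0.01)
  expect_identical(length(w@starts), 91L)          # floor((1-0.1)/0.01)+1
  expect_identical(as.integer(w@vectors[1, 1]), 3L)
  expect_identical(w@counts[1, 1], 3L)
  wt <- makeWindows(tr, "temporal", length = 0.1, stride = 0.01)
  expect_identical(ncol(wt@vectors), 200L)         # 100 ms at 0.5 ms bins
  expect_error(makeWindows(list(), "rate"), "non-empty")
  expect_error(makeWindows(tr, "rate", length = 2), "exceeds")
})

test_that("code distances match the direct Hann-norm oracle", {
  expect_equal(codeDistance(5, 2), 3)
  expect_equal(codeDistance(c(1, 2), c(1, 2)), 0)
  expect_error(codeDistance(1:3, 1:2), "dimensionality")
  # two single-spike temporal windows offset by more than the taper:
  # distance is sqrt(2) times the taper L2 norm
  a <- mkTrain(0.03, 0.1)
  b <- mkTrain(0.06, 0.1)
  wa <- makeWindows(a, "temporal", length = 0.1, stride = 0.1)
  wb <- makeWindows(b, "temporal", length = 0.1, stride = 0.1)
  d <- codeDistance(wa@vectors[1, ], wb@vectors[1, ])
  expect_equal(d, sqrt(2 * sum(oracleHann()^2)), tolerance = 1e-12)
})

test_that("code distance is a metric on random vectors", {
  set.seed(33)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15); z <- rnorm(15)
    expect_equal(codeDistance(x, y), codeDistance(y, x))
    expect_equal(codeDistance(x, x), 0)
    expect_lte(codeDistance(x, z),
               codeDistance(x, y) + codeDistance(y, z) + 1e-12)
  }
})

test_that("duplicating a unit scales distances by sqrt(2), order intact", {
  tr <- simulatePoisson(15, 2, seed = 3)
  w1 <- makeWindows(tr, "temporal", length = 0.1, stride = 0.05)
  w2 <- makeWindows(list(tr, tr), "temporal", length = 0.1, stride = 0.05)
  d1 <- as.matrix(dist(w1@vectors))
  d2 <- as.matrix(dist(w2@vectors))
  expect_equal(d2, sqrt(2) * d1, tolerance = 1e-12)
  ord1 <- order(d1[1, -1])
  ord2 <- order(d2[1, -1])
  expect_identical(ord1, ord2)
})

test_that("silence and spiking masks partition the windows", {
  quiet <- mkTrain(numeric(0), 1, "q")
  busy <- mkTrain(seq(0.05, 0.95, by = 0.1), 1, "b")
  w <- makeWindows(list(quiet), "rate", length = 0.1, stride = 0.05)
  expect_true(all(makeMask(w, "silence")@flags))
  expect_false(any(makeMask(w, "spiking")@flags))
  wb <- makeWindows(list(quiet, busy), "rate", length = 0.1, stride = 0.05)
  sil <- makeMask(wb, "silence")@flags
  spk <- makeMask(wb, "spiking")@flags
  expect_true(all(xor(sil, spk)))                  # exact partition
})

test_that("combinatorial masks demand two distinct units", {
  busy <- mkTrain(seq(0.05, 0.95, by = 0.1), 1, "b")
  w1 <- makeWindows(busy, "rate", length = 0.1, stride = 0.05)
  expect_error(makeMask(w1, "combinatorial"), "two units")
  # identical units: spiking on one and silence on the other is impossible
  w2 <- makeWindows(list(busy, busy), "rate", length = 0.1, stride = 0.05)
  expect_false(any(makeMask(w2, "combinatorial")@flags))
  expect_error(makeMask(w2, "combinatorial",
                        roles = list(spiker = 1, silent = 1)), "different")
  # asymmetric pair: flags match the count logic exactly
  quiet1 <- mkTrain(0.42, 1, "q")
  w3 <- makeWindows(list(busy, quiet1), "rate", length = 0.1, stride = 0.05)
  fl <- makeMask(w3, "combinatorial",
                 roles = list(spiker = "b", silent = "q"))@flags
  expect_identical(fl, w3@counts[, 1] >= 1L & w3@counts[, 2] == 0L)
})
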