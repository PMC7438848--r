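test_that("Signal Range and top-k mean follow their definitions", {
  expect_equal(signalRange(c(3, -1, 4, 1, 5)), 6)
  expect_equal(signalRange(rep(2, 50)), 0)
  x <- rnorm(100)
  expect_equal(signalRange(-x), signalRange(x))
  expect_equal(signalRange(x + 10), signalRange(x))
  expect_equal(signalRange(3 * x), 3 * signalRange(x))
  expect_error(signalRange(numeric(0)), "empty")
  expect_error(signalRange(c(1, Inf)), "non-finite")

  # 19 channels with ranges 1..19 -> mean of the 10 largest = 14.5
  X <- t(vapply(1:19, function(r) r * seq(0, 1, length.out = 64),
                numeric(64)))
  expect_equal(topkMeanRange(X), 14.5)
  Xc <- matrix(rep(seq(0, 7, length.out = 64), each = 19), nrow = 19,
               byrow = FALSE)
  expect_equal(topkMeanRange(Xc), 7)
  set.seed(8)
  Xr <- matrix(rnorm(19 * 256), 19)
  brute <- mean(sort(apply(Xr, 1, function(r) max(r) - min(r)),
                     decreasing = TRUE)[1:10])
  expect_equal(topkMeanRange(Xr), brute)
  expect_error(topkMeanRange(Xr, k = 20), "exceeds")
})

test_that("Welch PSD localises tones and satisfies Parseval", {
  fs <- 256
  tt <- (0:1023) / fs
  sp <- psdWelch(sin(2 * pi * 10 * tt), fs)
  expect_equal(sp$frequency[which.max(sp$density)], 10, tolerance = 0.025)

  set.seed(5)
  x <- rnorm(1024, sd = 3)
  sp2 <- psdWelch(x, fs)
  tot <- sum(diff(sp2$frequency) *
             (head(sp2$density, -1) + tail(sp2$density, -1)) / 2)
  expect_equal(tot, var(x), tolerance = 0.05 * var(x))

  # white noise is flat: band-averaged density ratio < 3 across 0.5-70 Hz
  bands <- cbind(seq(0.5, 60, by = 10), seq(10.5, 70, by = 10))
  ratios <- vapply(1:50, function(s) {
    spw <- psdWelch(fgnSim(0.5, 1024, seed = 900 + s), fs)
    e <- vapply(seq_len(nrow(bands)), function(b)
      bandEnergy(spw, bands[b, ], relative = FALSE) /
        diff(bands[b, ]), numeric(1))
    max(e) / min(e)
  }, numeric(1))
  expect_lt(mean(ratios), 3)

  expect_error(psdWelch(rnorm(100)), "256")
})

test_that("band energies integrate the PSD as specified", {
  fs <- 256
  tt <- (0:1023) / fs
  pure10 <- sin(2 * pi * 10 * tt)
  expect_gte(alphaEnergy(pure10, fs), 0.95)
  pure2 <- sin(2 * pi * 2 * tt)
  expect_lte(alphaEnergy(pure2, fs), 0.05)
  mix <- sin(2 * pi * 10 * tt) + sin(2 * pi * 20 * tt + 1)
  expect_equal(alphaEnergy(mix, fs), 0.5, tolerance = 0.05)

  # relative band energies over the five bands sum to <= 1, and to ~1 for
  # an in-band signal
  set.seed(6)
  x <- fgnSim(0.5, 1024, seed = 77)
  sp <- psdWelch(x, fs)
  sums <- sum(vapply(names(eegBands()), function(b)
    bandEnergy(sp, b, relative = TRUE), numeric(1)))
  expect_lte(sums, 1)
  inband <- sin(2 * pi * 10 * tt) + 0.5 * sin(2 * pi * 25 * tt)
  spi <- psdWelch(inband, fs)
  sums2 <- sum(vapply(names(eegBands()), function(b)
    bandEnergy(spi, b, relative = TRUE), numeric(1)))
  expect_equal(sums2, 1, tolerance = 0.05)

  expect_error(bandEnergy(sp, c(30, 20)), "invalid band")
})

test_that("Method One features behave on known inputs", {
  # 19 white-noise channels -> mean short-scale H near 0.5
  set.seed(10)
  Xw <- matrix(rnorm(19 * 1024), 19)
  f <- methodOneFeatures(EegEpoch(Xw, fs = 256))
  expect_equal(unname(f["mean_h"]), 0.5, tolerance = 0.1)
  expect_identical(f, methodOneFeatures(EegEpoch(Xw, fs = 256)))

  # planted high-amplitude spikes beat a quiet normal epoch's range
  cfg <- quietConfig(bgSd = 3, alphaAmpNormal = 2, alphaAmpDischarge = 2,
                     focalChannels = c("F7", "T3"))
  wins <- vapply(1:60, function(s) {
    d <- genEpoch("spike", cfg, seed = s,
                  templateArgs = list(amplitude = 150))
    n <- genEpoch("normal", cfg, seed = 1000 + s)
    methodOneFeatures(d)["signal_range"] >
      methodOneFeatures(n)["signal_range"]
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  expect_error(methodOneFeatures(EegEpoch(Xw[1:5, ], fs = 256)),
               "19-channel")
})
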