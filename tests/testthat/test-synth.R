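test_that("fGn simulation reproduces the theoretical autocovariance", {
  h <- 0.8
  n <- 4096
  lags <- 0:5
  # known-zero-mean estimator avoids the O(n^{2h-2}) mean-subtraction bias
  emp <- rowMeans(vapply(1:200, function(s) {
    x <- fgnSim(h, n, seed = s)
    vapply(lags, function(k) mean(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  }, numeric(length(lags))))
  theo <- fgnAutocov(h, lags)
  expect_lt(max(abs(emp - theo)), 0.02)
})

test_that("fGn at h = 0.5 is white and simulation is seed-deterministic", {
  n <- 4096
  x <- fgnSim(0.5, n, seed = 7)
  r1 <- stats::cor(x[-1], x[-n])
  expect_lt(abs(r1), 3 / sqrt(n))
  expect_identical(fgnSim(0.8, 512, sd = 3, seed = 11),
                   fgnSim(0.8, 512, sd = 3, seed = 11))
  expect_false(isTRUE(all.equal(fgnSim(0.8, 512, seed = 11),
                                fgnSim(0.8, 512, seed = 12))))
  expect_error(fgnSim(1.2, 100), "strictly in")
  expect_error(fgnSim(0.5, 1), ">= 2")
})

test_that("templates respect the clinical duration/amplitude definitions", {
  tpl <- makeTemplate("spike", fs = 256, durationMs = 40, amplitude = 100)
  expect_length(tpl$waveform, round(40 * 256 / 1000))
  expect_equal(signalRange(tpl$waveform), 100, tolerance = 0.05)

  for (kind in dischargeTypes()) {
    t0 <- makeTemplate(kind)   # defaults must satisfy the kind's own ranges
    expect_gt(length(t0$waveform), 1)
    expect_true(all(is.finite(t0$waveform)))
  }
  expect_error(makeTemplate("spike", durationMs = 10), "duration")
  expect_error(makeTemplate("spike", amplitude = 30), "amplitude")
  expect_error(makeTemplate("sharp", durationMs = 300), "duration")
  expect_error(makeTemplate("sharp", amplitude = 250), "amplitude")
  expect_error(makeTemplate("polyspike", nSpikes = 1), "two or more")
  expect_error(makeTemplate("spike_rhythm", freq = 30), "frequency")
  expect_error(makeTemplate("spike_rhythm", durationMs = 500), "duration")
})

test_that("spike-rhythm template has its dominant PSD peak at the drive rate", {
  tpl <- makeTemplate("spike_rhythm", fs = 256, durationMs = 1500, freq = 15)
  w <- tpl$waveform - mean(tpl$waveform)
  spec <- stats::spec.pgram(stats::ts(w, frequency = 256), taper = 0,
                            plot = FALSE)
  expect_equal(spec$freq[which.max(spec$spec)], 15, tolerance = 1 / 15)
})

test_that("epoch generation plants discharges on the focal channels", {
  # strong planted spikes on a quiet background: F7 (focal) must out-range
  # the distant Pz in nearly every epoch
  cfg <- quietConfig(bgSd = 15, focalChannels = c("F7", "T3"),
                     alphaAmpNormal = 5, alphaAmpDischarge = 5)
  hits <- vapply(1:100, function(s) {
    ep <- genEpoch("spike", cfg, seed = s,
                   templateArgs = list(amplitude = 150))
    X <- signals(ep)
    signalRange(X["F7", ]) > signalRange(X["Pz", ])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  epn <- genEpoch("normal", cfg, seed = 1)
  expect_identical(focalChannels(epn), character(0))
  expect_identical(epochLabel(epn), "normal")

  e1 <- genEpoch("sharp", synthConfig(), seed = 42)
  e2 <- genEpoch("sharp", synthConfig(), seed = 42)
  expect_identical(signals(e1), signals(e2))
  expect_identical(focalChannels(e1), focalChannels(e2))
})

test_that("dataset generation matches the requested catalog and is reproducible", {
  expect_identical(sum(defaultTypeCounts()), 540L)
  ds <- genDataset(3, stats::setNames(c(1, 2, 0, 0, 0, 0, 1),
                                      dischargeTypes()),
                   synthConfig(), seed = 5)
  expect_length(ds, 7)
  labs <- vapply(ds, epochLabel, "")
  expect_identical(sum(labs == "normal"), 3L)
  expect_identical(sum(labs == "sharp"), 2L)
  expect_identical(sum(labs == "spike_rhythm"), 1L)

  expect_identical(genDataset(0, rep(0L, 7), synthConfig(), seed = 1), list())

  ds2 <- genDataset(3, stats::setNames(c(1, 2, 0, 0, 0, 0, 1),
                                       dischargeTypes()),
                    synthConfig(), seed = 5)
  expect_identical(vapply(ds2, epochLabel, ""), labs)
  expect_identical(signals(ds2[[4]]), signals(ds[[4]]))
})

test_that("10-20 helpers are consistent", {
  expect_length(tenTwentyChannels(), 19)
  A <- tenTwentyAdjacency()
  expect_identical(A, t(A))
  d <- epidisc:::channelDistance("Cz")
  expect_identical(unname(d["Cz"]), 0)
  expect_true(all(is.finite(d)))   # layout is connected
})
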