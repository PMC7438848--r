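test_that("random-walk profile is the mean-removed cumulative sum", {
  p <- randomWalkProfile(c(1, 2, 3))
  expect_equal(p$u, c(-1, -1, 0))
  expect_equal(p$meanRemoved, 2)
  expect_equal(randomWalkProfile(rep(4.2, 10))$u, rep(0, 10))
  x <- rnorm(100)
  expect_lt(abs(randomWalkProfile(x)$u[100]), 1e-10)  # telescoping identity
  expect_error(randomWalkProfile(c(1, NA)), "non-finite")
  expect_error(randomWalkProfile(3), "length")
})

test_that("adaptive trend reproduces exact polynomials", {
  i <- 1:128
  for (w in c(9, 17, 33)) {
    expect_equal(globalTrend(2 * i + 3, w, order = 1), 2 * i + 3,
                 tolerance = 1e-8)
    expect_equal(globalTrend(i^2 - 5 * i, w, order = 2), i^2 - 5 * i,
                 tolerance = 1e-6)
  }
  expect_error(globalTrend(rnorm(64), 10, 1), "odd")
  expect_error(globalTrend(rnorm(8), 11, 1), "\\[3, length")
})

test_that("adaptive trend matches an independent implementation of the rule", {
  set.seed(14)
  for (case in list(c(64, 11, 1), c(100, 15, 2), c(257, 33, 2))) {
    u <- cumsum(rnorm(case[1]))
    expect_equal(globalTrend(u, case[2], case[3]),
                 refGlobalTrend(u, case[2], case[3]), tolerance = 1e-10)
  }
})

test_that("fluctuation is an RMS residual with the expected identities", {
  i <- 1:200
  expect_lt(fluctuation(2 * i + 1, 17, order = 1), 1e-8)
  set.seed(2)
  u <- cumsum(rnorm(200))
  f1 <- fluctuation(u, 17, order = 2)
  expect_equal(fluctuation(2 * u, 17, order = 2), 2 * f1,
               tolerance = 1e-12)
  v <- globalTrend(u, 17, order = 2)
  expect_equal(f1, sqrt(mean((u - v)^2)), tolerance = 1e-12)
  # translation equivariance of the trend
  expect_equal(globalTrend(u + 5, 17, 2), v + 5, tolerance = 1e-8)
})

test_that("scaling-curve slope recovers the Hurst exponent of fGn", {
  slopes <- vapply(1:20, function(s) {
    crv <- scalingCurve(fgnSim(0.75, 8192, seed = 300 + s), fit = FALSE)
    unname(stats::coef(stats::lm(crv@logF ~ log2(crv@w)))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - 0.75) < 0.07))
  expect_lt(abs(mean(slopes) - 0.75), 0.02)

  white <- vapply(1:20, function(s) {
    crv <- scalingCurve(rnorm(8192), fit = FALSE)
    unname(stats::coef(stats::lm(crv@logF ~ log2(crv@w)))[2])
  }, numeric(1))
  expect_lt(abs(mean(white) - 0.5), 0.05)

  expect_error(scalingCurve(rnorm(32)), "64")
})

test_that("two-regime fit recovers exact and noisy piecewise slopes", {
  lw <- seq(3, 8.5, by = 0.5)           # 12 grid points (log2 w)
  wodd <- round(2^lw)
  wodd <- wodd + (wodd %% 2 == 0)        # odd, strictly increasing grid
  crv <- new("ScalingCurve", w = as.numeric(wodd),
             logF = c(0.8 * log2(wodd[1:6]),
                      2 + 0.3 * log2(wodd[7:12])),   # discontinuous junction
             fitOrder = 2)
  fit <- fitTwoRegimes(crv)
  expect_equal(hurstShort(fit), 0.8, tolerance = 1e-9)
  expect_equal(hurstLong(fit), 0.3, tolerance = 1e-9)
  expect_identical(fit@breakpoint, 6L)

  lin <- new("ScalingCurve", w = as.numeric(wodd),
             logF = 0.6 * log2(wodd) + 1, fitOrder = 2)
  lfit <- fitTwoRegimes(lin)
  expect_lt(abs(hurstShort(lfit) - hurstLong(lfit)), 1e-6)
  expect_equal(hurstShort(lfit), 0.6, tolerance = 1e-9)

  set.seed(9)
  noisy <- crv
  noisy@logF <- crv@logF + rnorm(12, 0, 0.01)
  expect_equal(hurstShort(fitTwoRegimes(noisy)), 0.8, tolerance = 0.05)

  short <- new("ScalingCurve", w = as.numeric(wodd[1:5]),
               logF = crv@logF[1:5], fitOrder = 2)
  expect_error(fitTwoRegimes(short), "6 grid points")
})

test_that("batch Hurst matrix agrees with the single-series path", {
  set.seed(4)
  X <- vapply(1:8, function(i) fgnSim(runif(1, 0.2, 0.9), 512, seed = i),
              numeric(512))
  expect_equal(afaHurstMatrix(X),
               vapply(seq_len(ncol(X)), function(i) afaHurst(X[, i]),
                      numeric(1)),
               tolerance = 1e-12)
})
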