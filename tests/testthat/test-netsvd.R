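test_that("difference network vanishes for identical channels and matches toys", {
  Xc <- matrix(rep(sin(1:1024 / 10), each = 19), nrow = 19, byrow = FALSE)
  net <- differenceNetwork(EegEpoch(Xc, fs = 256), "signal_range")
  expect_equal(max(abs(networkMatrix(net))), 0)

  # 3-channel toy: constant 0, constant 1, unit ramp
  toy <- EegEpoch(rbind(a = rep(0, 128), b = rep(1, 128),
                        c = seq(0, 1, length.out = 128)), fs = 256)
  m <- networkMatrix(differenceNetwork(toy, "signal_range",
                                       strict = FALSE))
  expect_equal(m["a", "b"], 0)            # two constants differ by a constant
  expect_equal(m["a", "c"], 1)            # ramp range
  expect_equal(m["b", "c"], 1)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
})

test_that("difference network equals the brute-force double loop", {
  ep <- genEpoch("spike", synthConfig(), seed = 21)
  X <- signals(ep)
  for (feat in c("signal_range", "alpha_energy")) {
    A <- networkMatrix(differenceNetwork(ep, feat))
    fn <- if (feat == "signal_range") signalRange else
      function(x) alphaEnergy(x, fs = 256)
    B <- matrix(0, 19, 19)
    for (i in 1:19) for (j in 1:19)
      if (i != j) B[i, j] <- fn(X[i, ] - X[j, ])
    expect_equal(unname(A), B, tolerance = 1e-12)
    expect_equal(unname(A), t(unname(A)))   # symmetry from sign-flip invariance
  }
})

test_that("first singular value and vector follow the analytic cases", {
  a <- c(1, 2, 2)
  s <- firstSingular(a %*% t(a))
  expect_equal(s$sigma1, 9)                  # ||a||^2
  expect_equal(s$sigma1^2, 81)
  expect_equal(s$u1, a / 3)                  # sign fixed positive
  expect_equal(firstSingular(matrix(0, 4, 4))$sigma1, 0)

  set.seed(31)
  for (i in 1:50) {
    M <- matrix(rnorm(19 * 19), 19)
    M <- (M + t(M)) / 2
    expect_equal(firstSingular(M)$sigma1, max(abs(eigen(M)$values)),
                 tolerance = 1e-8)
  }
  expect_error(firstSingular(matrix(c(1, NA, 2, 3), 2)), "non-finite")
})

test_that("Method Two features scale and separate as expected", {
  Xc <- matrix(rep(cos(1:1024 / 7), each = 19), nrow = 19, byrow = FALSE)
  expect_equal(unname(methodTwoFeatures(EegEpoch(Xc, fs = 256))),
               c(0, 0, 0))

  ep <- genEpoch("sharp", synthConfig(), seed = 33)
  f <- methodTwoFeatures(ep)
  g <- 2.5
  eg <- EegEpoch(g * signals(ep), fs = 256)
  fg <- methodTwoFeatures(eg)
  expect_equal(unname(fg["s1sq_range"]), unname(g^2 * f["s1sq_range"]),
               tolerance = 1e-9)
  expect_equal(unname(fg["s1sq_hurst"]), unname(f["s1sq_hurst"]),
               tolerance = 1e-6)           # H is amplitude-invariant

  # permutation invariance of sigma1^2 under channel reordering
  A <- networkMatrix(differenceNetwork(ep, "signal_range"))
  p <- sample(19)
  expect_equal(firstSingular(A[p, p])$sigma1, firstSingular(A)$sigma1,
               tolerance = 1e-10)

  # planted discharges raise the range-network feature on average
  cfg <- quietConfig(bgSd = 10, focalChannels = c("T3", "T5"))
  vals <- vapply(1:40, function(s) {
    d <- genEpoch("spike", cfg, seed = s,
                  templateArgs = list(amplitude = 200))
    n <- genEpoch("normal", cfg, seed = 4000 + s)
    c(methodTwoFeatures(d)["s1sq_range"],
      methodTwoFeatures(n)["s1sq_range"])
  }, numeric(2))
  expect_gt(mean(vals[1, ]), mean(vals[2, ]))
})

test_that("heat-map export round-trips the matrix as CSV", {
  net <- differenceNetwork(genEpoch("normal", synthConfig(), seed = 2),
                           "signal_range")
  stem <- file.path(withr::local_tempdir(), "net")
  paths <- exportHeatmap(net, stem)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(utils::read.csv(paths[1], row.names = 1,
                                    check.names = FALSE))
  expect_equal(back, networkMatrix(net), tolerance = 1e-12)
  expect_identical(rownames(back), tenTwentyChannels())
})
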