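test_that("stratified split reproduces the cohort's train/test table", {
  labels <- c(rep("normal", 100), rep("discharge", 540))
  sp <- stratifiedSplit(labels, seed = 1)
  expect_identical(sum(labels[sp$train] == "normal"), 66L)
  expect_identical(sum(labels[sp$train] == "discharge"), 360L)
  expect_identical(sum(labels[sp$test] == "normal"), 34L)
  expect_identical(sum(labels[sp$test] == "discharge"), 180L)
  expect_length(sp$test, 214)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  tiny <- rep(c("a", "b"), each = 3)
  st <- stratifiedSplit(tiny, seed = 2)
  expect_identical(length(st$train), 4L)   # 2 per class
  expect_identical(length(st$test), 2L)

  expect_identical(stratifiedSplit(labels, seed = 9),
                   stratifiedSplit(labels, seed = 9))
  expect_error(stratifiedSplit(rep("a", 10)), "both classes")
  expect_error(stratifiedSplit(c(rep("a", 2), rep("b", 10))), "at least 3")
})

test_that("random forest separates separable toys and is null-calibrated", {
  set.seed(3)
  X <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 5), ncol = 2))
  y <- rep(c("normal", "spike"), each = 50)
  rf <- trainRf(X, y, seed = 4)
  acc <- mean((predictScores(rf, X) >= 0.5) == (y != "normal"))
  expect_equal(acc, 1)

  # pure-noise features -> test AUC near chance
  Xn <- matrix(rnorm(200 * 3), ncol = 3)
  yn <- rep(c("normal", "discharge"), each = 100)
  sp <- stratifiedSplit(yn, seed = 5)
  rfn <- trainRf(Xn[sp$train, ], yn[sp$train], seed = 6)
  auc <- rocAuc(predictScores(rfn, Xn[sp$test, ]), yn[sp$test])$auc
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)

  expect_error(trainRf(X, rep("spike", 100)), "single class")

  # repeated-split variance helper: separable toy stays at ceiling
  aucs <- repeatedSplitAuc(X, y, nRepeats = 5, nTrees = 50, seed = 8)
  expect_length(aucs, 5)
  expect_true(all(aucs > 0.9))
})

test_that("confusion counts tally the four cells", {
  truth <- c(rep("discharge", 180), rep("normal", 34))
  cm <- confusionCounts(truth, truth)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(180L, 0L, 0L, 34L))
  allPos <- confusionCounts(rep("discharge", 214), truth)
  expect_identical(allPos$fp, 34L)
  expect_identical(allPos$fn, 0L)

  set.seed(7)
  pred <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  tr <- sample(c(TRUE, FALSE), 100, replace = TRUE)
  cm2 <- confusionCounts(pred, tr)
  expect_identical(cm2$tp, sum(pred & tr))
  expect_identical(cm2$fn, sum(!pred & tr))
  expect_identical(cm2$fp, sum(pred & !tr))
  expect_identical(cm2$tn, sum(!pred & !tr))
  expect_identical(cm2$tp + cm2$fn + cm2$fp + cm2$tn, 100L)
  expect_error(confusionCounts(pred, tr[1:50]), "lengths differ")
})

test_that("sensitivity/specificity/accuracy follow their formulas exactly", {
  m1 <- classMetrics(list(tp = 175, fn = 5, fp = 6, tn = 28))
  expect_equal(round(100 * unname(m1), 2), c(97.22, 82.35, 94.86))
  m2 <- classMetrics(list(tp = 178, fn = 2, fp = 1, tn = 33))
  expect_equal(round(100 * unname(m2), 2), c(98.89, 97.06, 98.60))
  m3 <- classMetrics(list(tp = 10, fn = 10, fp = 10, tn = 10))
  expect_equal(unname(m3), c(0.5, 0.5, 0.5))
  expect_error(classMetrics(list(tp = 0, fn = 0, fp = 1, tn = 1)),
               "sensitivity undefined")
  expect_error(classMetrics(list(tp = 1, fn = 1, fp = 0, tn = 0)),
               "specificity undefined")
  # relabelling the positive class swaps sensitivity and specificity
  m4 <- classMetrics(list(tp = 28, fn = 6, fp = 5, tn = 175))
  expect_equal(m4[["sensitivity"]], m1[["specificity"]])
  expect_equal(m4[["specificity"]], m1[["sensitivity"]])
})

test_that("ROC/AUC equals pairwise concordance and is rank-invariant", {
  perfect <- rocAuc(c(0.9, 0.8, 0.2, 0.1), c("d", "d", "normal", "normal"))
  expect_equal(perfect$auc, 1)
  flat <- rocAuc(rep(0.5, 10), rep(c("d", "normal"), 5))
  expect_equal(flat$auc, 0.5)

  set.seed(11)
  scores <- round(runif(50), 2)            # ties included
  labels <- sample(c(TRUE, FALSE), 50, replace = TRUE, prob = c(0.6, 0.4))
  r <- rocAuc(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  conc <- mean(outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(r$auc, conc, tolerance = 1e-12)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  # invariance under strictly monotone transforms
  expect_equal(rocAuc(exp(3 * scores), labels)$auc, r$auc,
               tolerance = 1e-12)
  expect_error(rocAuc(scores, rep(TRUE, 50)), "both classes")
})
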