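#' Stratified train/test split
#'
#' Per class, `floor(trainFrac * n_class)` items are drawn (without
#' replacement, seed-deterministically) for training and the remainder kept
#' for testing; with the default 2/3 fraction, 100 normals and 540
#' discharges split into 66/360 training and 34/180 test items.
#'
#' @param labels factor or character vector of class labels.
#' @param trainFrac training fraction (default 2/3).
#' @param seed optional integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratifiedSplit <- function(labels, trainFrac = 2 / 3, seed = NULL) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("both classes must be present")
  if (any(tab < 3L)) stop("every class needs at least 3 members")
  withSeed(seed, {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      nTrain <- floor(trainFrac * length(idx))
      train <- c(train, sample(idx, nTrain))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train a random-forest discharge classifier
#'
#' Binary random forest (100 trees, impurity splits, unlimited depth) on a
#' numeric feature matrix; the positive class is `"discharge"`. Class
#' probabilities come from the fraction of tree votes.
#'
#' @param features numeric matrix/data.frame, one row per epoch.
#' @param labels binary labels; anything not `"normal"` is treated as the
#'   positive (discharge) class.
#' @param nTrees number of trees (default 100).
#' @param seed optional integer seed (forest is deterministic given it).
#' @return A fitted `randomForest` object.
#' @export
trainRf <- function(features, labels, nTrees = 100L, seed = NULL) {
  y <- factor(ifelse(as.character(labels) == "normal", "normal",
                     "discharge"),
              levels = c("normal", "discharge"))
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  X <- as.data.frame(features)
  stopifnot(all(vapply(X, is.numeric, logical(1))),
            all(is.finite(as.matrix(X))))
  withSeed(seed, randomForest::randomForest(X, y, ntree = nTrees))
}

#' Discharge probability scores from a fitted forest
#'
#' @param model a forest from [trainRf()].
#' @param features feature matrix/data.frame of new epochs.
#' @return Numeric vector of P(discharge) in `[0, 1]`.
#' @export
predictScores <- function(model, features) {
  stats::predict(model, as.data.frame(features),
                 type = "prob")[, "discharge"]
}

#' Confusion matrix counts
#'
#' Tallies TP/FN/FP/TN with the epileptiform discharge as the positive
#' class.
#'
#' @param predLabels predicted labels (`"discharge"`/`"normal"`, or logical
#'   with `TRUE` = discharge).
#' @param trueLabels true labels in the same convention.
#' @return List of class `ConfusionMatrix` with integer fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
confusionCounts <- function(predLabels, trueLabels) {
  if (length(predLabels) != length(trueLabels))
    stop("prediction and truth lengths differ")
  asPos <- function(x) {
    if (is.logical(x)) x else as.character(x) != "normal"
  }
  p <- asPos(predLabels)
  t <- asPos(trueLabels)
  structure(list(tp = sum(p & t), fn = sum(!p & t),
                 fp = sum(p & !t), tn = sum(!p & !t)),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("discharge", "normal"),
                              truth = c("discharge", "normal")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' \deqn{sensitivity = TP/(TP+FN), \quad specificity = TN/(TN+FP), \quad
#'   accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' A zero denominator is flagged as an error rather than silently returned
#' as 0.
#'
#' @param cm a `ConfusionMatrix` from [confusionCounts()] (or a list with
#'   fields tp, fn, fp, tn).
#' @return Named numeric vector (fractions in `[0, 1]`): sensitivity,
#'   specificity, accuracy.
#' @export
#' @examples
#' classMetrics(list(tp = 175, fn = 5, fp = 6, tn = 28)) * 100
classMetrics <- function(cm) {
  with(cm, {
    if (tp + fn == 0) stop("no positive cases: sensitivity undefined")
    if (tn + fp == 0) stop("no negative cases: specificity undefined")
    c(sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      accuracy = (tp + tn) / (tp + fp + tn + fn))
  })
}

#' Repeated-split AUC variance estimate
#'
#' Repeats the stratified split / train / score cycle under different
#' derived seeds and returns the test AUC of each repetition -- a quick
#' variance estimate around the single-split protocol.
#'
#' @param features numeric feature matrix.
#' @param labels class labels (`"normal"` vs discharge).
#' @param nRepeats number of repetitions (default 20).
#' @param trainFrac,nTrees as in [stratifiedSplit()] / [trainRf()].
#' @param seed master seed fanned out per repetition.
#' @return Numeric vector of `nRepeats` test AUCs.
#' @export
repeatedSplitAuc <- function(features, labels, nRepeats = 20L,
                             trainFrac = 2 / 3, nTrees = 100L, seed = 1L) {
  y <- ifelse(as.character(labels) == "normal", "normal", "discharge")
  seeds <- deriveSeeds(seed, 2L * nRepeats)
  vapply(seq_len(nRepeats), function(r) {
    sp <- stratifiedSplit(y, trainFrac, seed = seeds[2 * r - 1])
    model <- trainRf(features[sp$train, , drop = FALSE], y[sp$train],
                     nTrees = nTrees, seed = seeds[2 * r])
    rocAuc(predictScores(model, features[sp$test, , drop = FALSE]),
           y[sp$test])$auc
  }, numeric(1))
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds, returning the (FPR, TPR) staircase and the
#' trapezoidal area under it, which equals the Mann-Whitney concordance
#' probability with ties counted one half.
#'
#' @param scores numeric scores, larger = more discharge-like.
#' @param labels true labels (`"normal"` = negative, anything else
#'   positive, or logical).
#' @return List with `auc` and a data.frame `roc` (columns `fpr`, `tpr`,
#'   both monotone non-decreasing from 0 to 1).
#' @export
rocAuc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else as.character(labels) != "normal"
  nP <- sum(pos)
  nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tpSteps <- tapply(p, grp, sum)
  fpSteps <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tpSteps) / nP)
  fpr <- c(0, cumsum(fpSteps) / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = unname(auc), roc = data.frame(fpr = unname(fpr),
                                           tpr = unname(tpr)))
}
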