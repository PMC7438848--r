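#' End-to-end run configuration
#'
#' @param reference montage applied before feature extraction
#'   (`"earlobe"` passthrough -- the default, amplitude features being
#'   defined against the amplifier reference -- or `"average"`).
#' @param filter band-limit epochs (0.1-70 Hz + 50 Hz notch) before
#'   feature extraction (default TRUE).
#' @param order AFA detrending order.
#' @param relativeAlpha use relative alpha-band energy (default TRUE).
#' @param trainFrac training fraction for the stratified split.
#' @param nTrees random-forest size.
#' @param localization a [localizationConfig()].
#' @param seed master seed, fanned out to the per-stage seeds with
#'   [deriveSeeds()].
#' @return List of class `RunConfig`.
#' @export
runConfig <- function(reference = c("earlobe", "average"), filter = TRUE,
                      order = 2, relativeAlpha = TRUE, trainFrac = 2 / 3,
                      nTrees = 100L, localization = localizationConfig(),
                      seed = 1L) {
  structure(list(reference = match.arg(reference), filter = filter,
                 order = order, relativeAlpha = relativeAlpha,
                 trainFrac = trainFrac, nTrees = nTrees,
                 localization = localization, seed = seed),
            class = "RunConfig")
}

prepEpoch <- function(epoch, config) {
  if (config$reference == "average") epoch <- applyReference(epoch, "average")
  if (config$filter) epoch <- filterEpoch(epoch)
  epoch
}

classifyFeatures <- function(feat, labels, config) {
  seeds <- deriveSeeds(config$seed, 2L)
  split <- stratifiedSplit(ifelse(labels == "normal", "normal", "discharge"),
                           trainFrac = config$trainFrac, seed = seeds[1])
  model <- trainRf(feat[split$train, , drop = FALSE], labels[split$train],
                   nTrees = config$nTrees, seed = seeds[2])
  scores <- predictScores(model, feat[split$test, , drop = FALSE])
  truth <- ifelse(labels[split$test] == "normal", "normal", "discharge")
  pred <- ifelse(scores >= 0.5, "discharge", "normal")
  cm <- confusionCounts(pred, truth)
  ra <- rocAuc(scores, truth)
  list(split = split, model = model, scores = scores,
       confusion = cm, metrics = classMetrics(cm), auc = ra$auc,
       roc = ra$roc)
}

#' Run the amplitude-and-Hurst detection method end to end
#'
#' Extracts the Method One feature pair (top-10 mean Signal Range, mean
#' short-scale Hurst exponent) from every labeled epoch, performs the
#' stratified 2/3 split, trains the random forest and evaluates on the
#' held-out third. Fully deterministic given `config$seed`.
#'
#' @param epochs list of labeled [EegEpoch-class] objects (both classes
#'   present).
#' @param config a [runConfig()].
#' @return List with `features` (data.frame: epoch, signal_range, mean_h,
#'   label), `split`, `model`, `scores`, `confusion`, `metrics`, `auc`,
#'   `roc`.
#' @export
runMethodOne <- function(epochs, config = runConfig()) {
  labels <- vapply(epochs, epochLabel, "")
  if (length(unique(labels == "normal")) < 2L)
    stop("both normal and discharge epochs are required")
  feat <- t(vapply(epochs,
                   function(e) methodOneFeatures(prepEpoch(e, config),
                                                 order = config$order),
                   numeric(2)))
  res <- classifyFeatures(feat, labels, config)
  res$features <- data.frame(epoch = seq_along(epochs), feat,
                             label = labels)
  res
}

#' Run the network-SVD detection method end to end
#'
#' As [runMethodOne()], with the three first-singular-value-squared network
#' features. Degenerate (all-constant-channel) epochs yield all-zero
#' networks and are flagged with a warning rather than silently scored.
#'
#' @inheritParams runMethodOne
#' @return As [runMethodOne()], with feature columns `s1sq_range`,
#'   `s1sq_alpha`, `s1sq_hurst`.
#' @export
runMethodTwo <- function(epochs, config = runConfig()) {
  labels <- vapply(epochs, epochLabel, "")
  if (length(unique(labels == "normal")) < 2L)
    stop("both normal and discharge epochs are required")
  feat <- t(vapply(epochs,
                   function(e) methodTwoFeatures(prepEpoch(e, config),
                                                 relative = config$relativeAlpha,
                                                 order = config$order),
                   numeric(3)))
  if (any(rowSums(abs(feat)) == 0))
    warning("degenerate epoch(s) with all-zero networks: ",
            paste(which(rowSums(abs(feat)) == 0), collapse = ", "))
  res <- classifyFeatures(feat, labels, config)
  res$features <- data.frame(epoch = seq_along(epochs), feat,
                             label = labels)
  res
}

#' Cohort localization per discharge type
#'
#' Groups discharge epochs by type, localizes each epoch (subject) via the
#' three-network singular-vector projection, and reports the cohort-level
#' channel set per type.
#'
#' @param epochs list of labeled [EegEpoch-class] objects; normals are
#'   ignored.
#' @param config a [runConfig()].
#' @param subjects optional vector of subject identifiers (one per epoch).
#'   When given, the channel sets of a subject's epochs of one type are
#'   merged by union before the cohort vote, so each subject counts once;
#'   by default every epoch is its own subject.
#' @return data.frame with columns `type`, `channels`
#'   (semicolon-separated), `nSubjects`.
#' @export
runLocalization <- function(epochs, config = runConfig(), subjects = NULL) {
  labels <- vapply(epochs, epochLabel, "")
  if (is.null(subjects)) subjects <- seq_along(epochs)
  stopifnot(length(subjects) == length(epochs))
  keep <- labels %in% dischargeTypes()
  if (!any(keep)) stop("no discharge epochs to localize")
  epochs <- epochs[keep]
  labels <- labels[keep]
  subjects <- subjects[keep]
  types <- intersect(dischargeTypes(), unique(labels))
  rows <- lapply(types, function(ty) {
    subj <- epochs[labels == ty]
    sets <- lapply(subj, function(e)
      subjectLocalization(epochNetworks(prepEpoch(e, config),
                                        relative = config$relativeAlpha,
                                        order = config$order),
                          config$localization))
    sets <- unname(lapply(split(sets, subjects[labels == ty]),
                          function(g) Reduce(union, g)))
    data.frame(type = ty,
               channels = paste(cohortLocalization(sets,
                                                   config$localization),
                                collapse = ";"),
               nSubjects = length(sets))
  })
  do.call(rbind, rows)
}

#' 2-D phase diagram of an epoch's channel-sum series
#'
#' Delay embedding `(s(t), s(t + lag))` of the sum over channels; the range
#' of either coordinate equals the Signal Range of the summed series.
#'
#' @param epoch an [EegEpoch-class].
#' @param lag embedding delay in samples (default 1).
#' @return data.frame with columns `x` = s(t) and `y` = s(t + lag),
#'   `N - lag` rows.
#' @export
phaseDiagram <- function(epoch, lag = 1L) {
  s <- colSums(signals(epoch))
  lag <- as.integer(lag)
  if (lag < 1L || lag >= length(s))
    stop("lag must lie in [1, length - 1]")
  n <- length(s)
  data.frame(x = s[1:(n - lag)], y = s[(1 + lag):n])
}
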