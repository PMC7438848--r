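#' Localization thresholds
#'
#' @param projectionThreshold minimum absolute projection coefficient
#'   (cosine) between a network column and the first singular vector for
#'   the channel to be retained (default 0.5).
#' @param cohortProbability minimum frequency with which a channel must
#'   appear across a cohort's per-subject sets to be retained (default
#'   0.55).
#' @param mode `"cosine"` projects normalised columns (unit-independent;
#'   default); `"dot"` uses the raw dot product.
#' @param combine `"intersection"` of the three per-network channel sets
#'   (default) or `"majority"` (kept by at least 2 of 3 networks).
#' @return List of class `LocalizationConfig`.
#' @export
localizationConfig <- function(projectionThreshold = 0.5,
                               cohortProbability = 0.55,
                               mode = c("cosine", "dot"),
                               combine = c("intersection", "majority")) {
  stopifnot(projectionThreshold > 0, projectionThreshold <= 1,
            cohortProbability > 0, cohortProbability <= 1)
  structure(list(projectionThreshold = projectionThreshold,
                 cohortProbability = cohortProbability,
                 mode = match.arg(mode), combine = match.arg(combine)),
            class = "LocalizationConfig")
}

#' Channels aligned with a network's first singular vector
#'
#' Projects each column of the network onto the first (left) singular
#' vector and retains channel j when the absolute projection coefficient
#' is at least `threshold`. In the default cosine mode the column is
#' normalised first, so the coefficient is `|cos(column_j, u1)|` and the
#' 0.5 threshold is unit-independent; zero columns are never retained.
#'
#' @param network a [FeatureNetwork-class] or plain square matrix.
#' @param u1 unit first singular vector (default: computed from the
#'   network via [firstSingular()]).
#' @param threshold retention threshold (default 0.5).
#' @param mode `"cosine"` (default) or `"dot"`.
#' @return Character vector of retained channel names (column indices as
#'   names for a plain matrix).
#' @export
selectChannels <- function(network, u1 = NULL, threshold = 0.5,
                           mode = c("cosine", "dot")) {
  mode <- match.arg(mode)
  A <- if (is(network, "FeatureNetwork")) network@matrix else network
  ch <- if (is(network, "FeatureNetwork")) channelNames(network)
        else (colnames(A) %||% as.character(seq_len(ncol(A))))
  if (is.null(u1)) u1 <- firstSingular(A)$u1
  if (length(u1) != nrow(A)) stop("u1 length does not match the network")
  norms <- sqrt(colSums(A^2))
  proj <- abs(drop(crossprod(A, u1)))
  coef <- if (mode == "cosine") ifelse(norms > 0, proj / norms, 0) else proj
  ch[coef >= threshold & norms > 0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-subject discharge localization
#'
#' Applies [selectChannels()] to each of the subject's three
#' channel-difference networks and combines the per-network channel sets --
#' by default the channels common to all three.
#'
#' @param networks list of the three [FeatureNetwork-class] objects of one
#'   epoch/subject (as from [epochNetworks()]).
#' @param config a [localizationConfig()].
#' @return Character vector of channel names.
#' @export
subjectLocalization <- function(networks, config = localizationConfig()) {
  sets <- lapply(networks, selectChannels,
                 threshold = config$projectionThreshold, mode = config$mode)
  if (config$combine == "intersection")
    return(Reduce(intersect, sets))
  tab <- table(unlist(sets))
  names(tab)[tab >= 2]
}

#' Cohort-level discharge localization
#'
#' A channel is retained when it appears in at least
#' `cohortProbability` of the per-subject channel sets.
#'
#' @param subjectSets non-empty list of per-subject channel-name vectors.
#' @param config a [localizationConfig()].
#' @return Character vector of channel names, in 10-20 order when
#'   applicable.
#' @export
cohortLocalization <- function(subjectSets, config = localizationConfig()) {
  if (!length(subjectSets)) stop("empty cohort")
  freq <- table(unlist(lapply(subjectSets, unique)))
  keep <- names(freq)[freq / length(subjectSets) >= config$cohortProbability]
  ord <- tenTwentyChannels()
  c(keep[order(match(keep, ord))])
}
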