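#' EegEpoch: one multichannel EEG epoch
#'
#' Container for a single fixed-length EEG epoch: a channel-by-sample matrix
#' in microvolts, its sampling rate, ordered channel names, an optional class
#' label (`"normal"` or one of [dischargeTypes()]) and, for synthetic epochs,
#' the ground-truth focal channel set.
#'
#' The standard clinical epoch is 19 channels ([tenTwentyChannels()]) of
#' 4 s at 256 Hz; reduced channel sets are permitted for toy examples, and
#' operations that require the full montage check for it explicitly.
#'
#' @slot signals numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character, one name per row of `signals`.
#' @slot label character, `"normal"`, a discharge type, or `NA`.
#' @slot focalChannels character, ground-truth focal channels (may be empty).
#' @exportClass EegEpoch
setClass("EegEpoch",
  representation(signals = "matrix", fs = "numeric",
                 channelNames = "character", label = "character",
                 focalChannels = "character"),
  prototype(label = NA_character_, focalChannels = character(0)))

setValidity("EegEpoch", function(object) {
  msg <- character(0)
  if (!is.numeric(object@signals)) msg <- c(msg, "signals must be numeric")
  if (length(object@channelNames) != nrow(object@signals))
    msg <- c(msg, "one channel name per signal row required")
  if (anyDuplicated(object@channelNames))
    msg <- c(msg, "duplicated channel names")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!all(is.finite(object@signals)))
    msg <- c(msg, "signals contain non-finite values")
  if (!all(object@focalChannels %in% object@channelNames))
    msg <- c(msg, "focalChannels must be a subset of channelNames")
  if (length(msg)) msg else TRUE
})

#' Construct an EegEpoch
#'
#' @param signals channels-by-samples numeric matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames channel names in row order; defaults to the rownames
#'   of `signals`, or to [tenTwentyChannels()] for 19-row input.
#' @param label optional class label.
#' @param focalChannels optional ground-truth focal channels.
#' @return An [EegEpoch-class] object.
#' @export
EegEpoch <- function(signals, fs = 256, channelNames = NULL,
                     label = NA_character_, focalChannels = character(0)) {
  if (is.null(channelNames)) {
    channelNames <- rownames(signals)
    if (is.null(channelNames) && nrow(signals) == 19L)
      channelNames <- tenTwentyChannels()
    if (is.null(channelNames))
      channelNames <- paste0("ch", seq_len(nrow(signals)))
  }
  rownames(signals) <- channelNames
  new("EegEpoch", signals = signals, fs = fs, channelNames = channelNames,
      label = as.character(label), focalChannels = focalChannels)
}

#' Recording: a continuous multichannel EEG recording
#'
#' @slot signals numeric matrix, channels x samples, microvolts.
#' @slot fs sampling rate in Hz.
#' @slot channelNames character vector.
#' @slot reference reference scheme: "earlobe", "average" or "raw".
#' @exportClass Recording
setClass("Recording",
  representation(signals = "matrix", fs = "numeric",
                 channelNames = "character", reference = "character"),
  prototype(reference = "raw"))

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@channelNames) != nrow(object@signals))
    msg <- c(msg, "one channel name per signal row required")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!object@reference %in% c("earlobe", "average", "raw"))
    msg <- c(msg, "reference must be earlobe, average or raw")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param signals channels-by-samples matrix (microvolts).
#' @param fs sampling rate, Hz.
#' @param channelNames channel names; defaults as for [EegEpoch()].
#' @param reference reference scheme label.
#' @return A [Recording-class] object.
#' @export
Recording <- function(signals, fs = 256, channelNames = NULL,
                      reference = "raw") {
  if (is.null(channelNames)) {
    channelNames <- rownames(signals)
    if (is.null(channelNames) && nrow(signals) == 19L)
      channelNames <- tenTwentyChannels()
  }
  rownames(signals) <- channelNames
  new("Recording", signals = signals, fs = fs,
      channelNames = channelNames, reference = reference)
}

#' ScalingCurve: AFA log-log fluctuation curve with two-regime fit
#'
#' Holds the paired (log2 w, log2 F(w)) points produced by adaptive fractal
#' analysis together with the two-segment linear fit: the short-scale and
#' long-scale Hurst estimates and the breakpoint index separating them.
#'
#' @slot w odd window sizes (samples).
#' @slot logF log2 of the fluctuation function at each window size.
#' @slot hShort short-scale slope (Hurst estimate used downstream).
#' @slot hLong long-scale slope.
#' @slot breakpoint index into `w` of the last point of the short segment
#'   (NA before fitting).
#' @slot fitOrder polynomial detrending order M (1 or 2).
#' @exportClass ScalingCurve
setClass("ScalingCurve",
  representation(w = "numeric", logF = "numeric", hShort = "numeric",
                 hLong = "numeric", breakpoint = "numeric",
                 fitOrder = "numeric"),
  prototype(hShort = NA_real_, hLong = NA_real_, breakpoint = NA_real_))

setValidity("ScalingCurve", function(object) {
  msg <- character(0)
  if (length(object@w) != length(object@logF))
    msg <- c(msg, "w and logF must have equal length")
  if (any(object@w %% 2 == 0)) msg <- c(msg, "window sizes must be odd")
  if (is.unsorted(object@w, strictly = TRUE))
    msg <- c(msg, "window sizes must be strictly increasing")
  if (!all(is.finite(object@logF))) msg <- c(msg, "logF must be finite")
  if (length(msg)) msg else TRUE
})

#' FeatureNetwork: channel-difference feature matrix
#'
#' A symmetric channels-by-channels matrix whose (i, j) entry is a scalar
#' feature (Signal Range, relative alpha-band energy, or short-scale Hurst
#' exponent) of the difference series `channel_i - channel_j`. The diagonal
#' (a channel minus itself) is zero by convention.
#'
#' @slot matrix symmetric numeric matrix with zero diagonal.
#' @slot feature one of "signal_range", "alpha_energy", "hurst".
#' @slot channelNames channel names in matrix order.
#' @exportClass FeatureNetwork
setClass("FeatureNetwork",
  representation(matrix = "matrix", feature = "character",
                 channelNames = "character"))

setValidity("FeatureNetwork", function(object) {
  msg <- character(0)
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (length(object@channelNames) != nrow(m))
    msg <- c(msg, "channelNames length must match matrix dimension")
  if (!all(is.finite(m))) msg <- c(msg, "matrix has non-finite entries")
  else {
    if (max(abs(m - t(m))) >= 1e-9) msg <- c(msg, "matrix must be symmetric")
    if (max(abs(diag(m))) >= 1e-12) msg <- c(msg, "diagonal must be zero")
  }
  if (!object@feature %in% c("signal_range", "alpha_energy", "hurst"))
    msg <- c(msg, "unknown feature kind")
  if (object@feature %in% c("signal_range", "alpha_energy") &&
      all(is.finite(m)) && min(m) < -1e-9)
    msg <- c(msg, "entries must be non-negative for this feature")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EegEpoch", function(object) {
  cat(sprintf("EegEpoch: %d channels x %d samples @ %g Hz (%.3g s)\n",
              nrow(object@signals), ncol(object@signals), object@fs,
              ncol(object@signals) / object@fs))
  cat("  label:", object@label, "\n")
  if (length(object@focalChannels))
    cat("  focal:", paste(object@focalChannels, collapse = ", "), "\n")
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz, reference=%s\n",
              nrow(object@signals), ncol(object@signals), object@fs,
              object@reference))
})

setMethod("show", "ScalingCurve", function(object) {
  cat(sprintf("ScalingCurve: %d window sizes in [%g, %g] (order M=%g)\n",
              length(object@w), min(object@w), max(object@w),
              object@fitOrder))
  if (!is.na(object@hShort))
    cat(sprintf("  h_short=%.3f  h_long=%.3f  breakpoint at w=%g\n",
                object@hShort, object@hLong, object@w[object@breakpoint]))
})

setMethod("show", "FeatureNetwork", function(object) {
  cat(sprintf("FeatureNetwork (%s): %dx%d, max entry %.4g\n",
              object@feature, nrow(object@matrix), ncol(object@matrix),
              max(object@matrix)))
})

#' @describeIn EegEpoch-class channel-by-sample signal matrix
#' @param object an object of the documented class
#' @export
setGeneric("signals", function(object) standardGeneric("signals"))
#' @rdname EegEpoch-class
#' @export
setMethod("signals", "EegEpoch", function(object) object@signals)
#' @rdname Recording-class
#' @export
setMethod("signals", "Recording", function(object) object@signals)

#' @describeIn EegEpoch-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EegEpoch-class
#' @export
setMethod("samplingRate", "EegEpoch", function(object) object@fs)
#' @rdname Recording-class
#' @export
setMethod("samplingRate", "Recording", function(object) object@fs)

#' @describeIn EegEpoch-class ordered channel names
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname EegEpoch-class
#' @export
setMethod("channelNames", "EegEpoch", function(object) object@channelNames)
#' @rdname Recording-class
#' @export
setMethod("channelNames", "Recording", function(object) object@channelNames)
#' @rdname FeatureNetwork-class
#' @export
setMethod("channelNames", "FeatureNetwork",
          function(object) object@channelNames)

#' @describeIn EegEpoch-class class label ("normal", a discharge type, or NA)
#' @export
setGeneric("epochLabel", function(object) standardGeneric("epochLabel"))
#' @rdname EegEpoch-class
#' @export
setMethod("epochLabel", "EegEpoch", function(object) object@label)

#' @describeIn EegEpoch-class ground-truth focal channels of a synthetic epoch
#' @export
setGeneric("focalChannels", function(object) standardGeneric("focalChannels"))
#' @rdname EegEpoch-class
#' @export
setMethod("focalChannels", "EegEpoch", function(object) object@focalChannels)

#' @describeIn FeatureNetwork-class the feature matrix itself
#' @param object an object of the documented class
#' @export
setGeneric("networkMatrix", function(object) standardGeneric("networkMatrix"))
#' @rdname FeatureNetwork-class
#' @export
setMethod("networkMatrix", "FeatureNetwork", function(object) {
  m <- object@matrix
  dimnames(m) <- list(object@channelNames, object@channelNames)
  m
})

#' @describeIn ScalingCurve-class short-scale Hurst estimate
#' @param object an object of the documented class
#' @export
setGeneric("hurstShort", function(object) standardGeneric("hurstShort"))
#' @rdname ScalingCurve-class
#' @export
setMethod("hurstShort", "ScalingCurve", function(object) object@hShort)

#' @describeIn ScalingCurve-class long-scale Hurst estimate
#' @export
setGeneric("hurstLong", function(object) standardGeneric("hurstLong"))
#' @rdname ScalingCurve-class
#' @export
setMethod("hurstLong", "ScalingCurve", function(object) object@hLong)

#' Coerce a ScalingCurve to a data.frame of (w, log2 w, log2 F) points
#'
#' @param x a ScalingCurve
#' @param ... unused
#' @export
as.data.frame.ScalingCurve <- function(x, ...) {
  data.frame(w = x@w, log2w = log2(x@w), log2F = x@logF)
}
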