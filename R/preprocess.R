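#' Re-reference a recording or epoch
#'
#' `"average"` subtracts the instantaneous mean across channels from every
#' channel (the average montage used for clinical annotation);
#' `"earlobe"` is a passthrough -- amplifier-referenced input is assumed to
#' already be expressed against the earlobes, and no re-referencing is
#' attempted without earlobe channels.
#'
#' @param x a [Recording-class] or [EegEpoch-class].
#' @param mode `"average"` or `"earlobe"`.
#' @return An object of the same class as `x`.
#' @export
applyReference <- function(x, mode = c("average", "earlobe")) {
  mode <- match.arg(mode)
  if (mode == "earlobe") return(x)
  X <- signals(x)
  X <- sweep(X, 2, colMeans(X))
  if (is(x, "Recording"))
    Recording(X, fs = samplingRate(x), channelNames = channelNames(x),
              reference = "average")
  else
    EegEpoch(X, fs = samplingRate(x), channelNames = channelNames(x),
             label = epochLabel(x), focalChannels = focalChannels(x))
}

# RBJ biquad notch, quality factor q, as an Arma filter for signal::filtfilt
notchBiquad <- function(freq, fs, q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

#' Band-limit an epoch (zero-phase)
#'
#' Applies the study acquisition band digitally: the epoch mean is removed,
#' then a zero-phase (forward-backward) Butterworth high-pass at `low`,
#' low-pass at `high`, and a narrow notch (quality 30) at `notch`. Zero
#' phase preserves the morphology of the sharp transients that the Signal
#' Range feature depends on.
#'
#' @param epoch an [EegEpoch-class] (or [Recording-class]).
#' @param low high-pass edge, Hz (default 0.1).
#' @param high low-pass edge, Hz (default 70).
#' @param notch mains notch frequency, Hz (default 50); `NA` disables it.
#' @return Filtered object of the same class and shape.
#' @export
filterEpoch <- function(epoch, low = 0.1, high = 70, notch = 50) {
  fs <- samplingRate(epoch)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (!is.na(notch) && !(notch > low && notch < high))
    stop("notch must lie inside (low, high), or be NA to disable")
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  nt <- if (!is.na(notch)) notchBiquad(notch, fs) else NULL
  X <- signals(epoch)
  for (i in seq_len(nrow(X))) {
    y <- X[i, ] - mean(X[i, ])
    y <- signal::filtfilt(hp, y)
    y <- signal::filtfilt(lp, y)
    if (!is.null(nt)) y <- signal::filtfilt(nt, y)
    X[i, ] <- y
  }
  if (is(epoch, "Recording"))
    Recording(X, fs = fs, channelNames = channelNames(epoch),
              reference = epoch@reference)
  else
    EegEpoch(X, fs = fs, channelNames = channelNames(epoch),
             label = epochLabel(epoch), focalChannels = focalChannels(epoch))
}

#' Cut a recording into consecutive fixed-length epochs
#'
#' Non-overlapping consecutive epochs of `epochLen` seconds; a trailing
#' partial epoch is discarded. A recording shorter than one epoch is an
#' error.
#'
#' @param recording a [Recording-class].
#' @param epochLen epoch length in seconds (default 4).
#' @return List of [EegEpoch-class] objects.
#' @export
segmentEpochs <- function(recording, epochLen = 4) {
  fs <- samplingRate(recording)
  nEp <- as.integer(round(fs * epochLen))
  X <- signals(recording)
  k <- ncol(X) %/% nEp
  if (k < 1L) stop("recording is shorter than one epoch")
  lapply(seq_len(k), function(i)
    EegEpoch(X[, ((i - 1L) * nEp + 1L):(i * nEp), drop = FALSE], fs = fs,
             channelNames = channelNames(recording)))
}
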