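#' Signal Range of a series
#'
#' The simplest amplitude statistic: maximum minus minimum over the whole
#' epoch. Invariant under sign flip and constant shift; scales linearly
#' with gain.
#'
#' @param x non-empty finite numeric series.
#' @return `max(x) - min(x) >= 0`, in the units of `x` (microvolts for EEG).
#' @export
#' @examples
#' signalRange(c(3, -1, 4, 1, 5))  # 6
signalRange <- function(x) {
  stopIfNotFinite(x, "series")
  max(x) - min(x)
}

#' Mean of the k largest per-channel Signal Ranges
#'
#' The epoch-level amplitude feature: per-channel Signal Ranges are sorted
#' and the largest `k` (default 10 of the 19 channels) averaged.
#'
#' @param epoch an [EegEpoch-class] (or plain channels-by-samples matrix).
#' @param k how many of the largest ranges to average (default 10).
#' @return Mean of the `k` largest per-channel ranges, microvolts.
#' @export
topkMeanRange <- function(epoch, k = 10L) {
  X <- if (is(epoch, "EegEpoch")) signals(epoch) else epoch
  if (k > nrow(X)) stop("k exceeds the number of channels (", nrow(X), ")")
  stopIfNotFinite(X, "epoch signals")
  r <- colRangeCpp(t(X))
  mean(sort(r, decreasing = TRUE)[seq_len(k)])
}

#' Welch power spectral density
#'
#' Averaged-periodogram PSD: the series is cut into `segLen`-second Hann
#' tapered segments with 50% overlap, each segment mean-removed, and the
#' one-sided periodograms averaged. Normalised so that the integral of the
#' density approximates the variance of the (detrended) series.
#'
#' @param x numeric series, length >= 256.
#' @param fs sampling rate, Hz.
#' @param segLen segment length in seconds (default 1).
#' @return data.frame with columns `frequency` (Hz) and `density`
#'   (microvolts squared per Hz).
#' @export
psdWelch <- function(x, fs = 256, segLen = 1) {
  if (length(x) < 256L) stop("series must have at least 256 samples")
  stopIfNotFinite(x, "series")
  wd <- welchDensityMatrix(matrix(x, ncol = 1L), fs, segLen)
  data.frame(frequency = wd$frequency, density = wd$density[, 1L])
}

# Welch density for every column of X at once (same estimator as psdWelch);
# returns list(frequency, density matrix of dim (nseg/2 + 1) x ncol(X))
welchDensityMatrix <- function(X, fs, segLen = 1) {
  nseg <- as.integer(round(segLen * fs))
  step <- nseg %/% 2L
  starts <- seq(1L, nrow(X) - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * (seq_len(nseg) - 1) / (nseg - 1)))
  U <- sum(win^2)
  half <- nseg %/% 2L
  S <- ncol(X)
  idx1 <- seq_len(half + 1L)
  idxRev <- c(1L, nseg:(half + 1L))
  acc <- matrix(0, half + 1L, S + S %% 2L)
  for (s in starts) {
    seg <- X[s:(s + nseg - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg)) * win
    if (S %% 2L) seg <- cbind(seg, 0)
    # two real FFTs per complex FFT: pack column pairs re + i*im
    odd <- seq(1L, ncol(seg), by = 2L)
    Z <- stats::mvfft(seg[, odd, drop = FALSE] +
                      1i * seg[, odd + 1L, drop = FALSE])
    A <- Z[idx1, , drop = FALSE]
    B <- Conj(Z[idxRev, , drop = FALSE])
    P <- matrix(0, half + 1L, ncol(acc))
    P[, odd] <- Mod(A + B)^2 / 4
    P[, odd + 1L] <- Mod(A - B)^2 / 4
    P <- P / (fs * U)
    P[2:half, ] <- 2 * P[2:half, ]
    acc <- acc + P
  }
  list(frequency = (0:half) * fs / nseg,
       density = acc[, seq_len(S), drop = FALSE] / length(starts))
}

# weights w such that w %*% density reproduces trapezoidBand(·, lo, hi)
bandWeightVector <- function(f, lo, hi) {
  hi <- min(hi, max(f))
  lo <- max(lo, min(f))
  n <- length(f)
  if (hi <= lo) return(numeric(n))
  ff <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  W <- matrix(0, length(ff), n)              # linear interpolation at ff
  for (j in seq_along(ff)) {
    k <- findInterval(ff[j], f)
    if (f[k] == ff[j]) W[j, k] <- 1
    else {
      t <- (ff[j] - f[k]) / (f[k + 1] - f[k])
      W[j, k] <- 1 - t
      W[j, k + 1] <- t
    }
  }
  cw <- numeric(length(ff))                  # trapezoid coefficients
  dx <- diff(ff)
  cw[-length(ff)] <- dx / 2
  cw[-1] <- cw[-1] + dx / 2
  drop(cw %*% W)
}

# relative (or absolute) alpha energy for every column of X
alphaEnergyMatrix <- function(X, fs, relative = TRUE) {
  wd <- welchDensityMatrix(X, fs)
  e <- drop(bandWeightVector(wd$frequency, 8, 13) %*% wd$density)
  if (relative) {
    tot <- drop(bandWeightVector(wd$frequency, 0.5, 70) %*% wd$density)
    e <- ifelse(tot > 0, e / tot, 0)
  }
  e
}

#' Standard clinical EEG frequency bands
#'
#' delta 0.5-3, theta 4-7, alpha 8-13, beta 14-30, gamma 30-70 Hz (the
#' gamma upper edge capped at the 70 Hz acquisition bandwidth).
#'
#' @return Named list of `c(lo, hi)` pairs in Hz.
#' @export
eegBands <- function() {
  list(delta = c(0.5, 3), theta = c(4, 7), alpha = c(8, 13),
       beta = c(14, 30), gamma = c(30, 70))
}

#' Band energy from a PSD
#'
#' Trapezoidal integral of the spectral density over `[lo, hi]`; with
#' `relative = TRUE` (default) divided by the integral over the full
#' 0.5-70 Hz acquisition band, giving a relative energy in `[0, 1]`.
#'
#' @param spectrum data.frame from [psdWelch()] (columns `frequency`,
#'   `density`).
#' @param band a `c(lo, hi)` pair in Hz, or a band name from [eegBands()]
#'   (default `"alpha"`).
#' @param relative divide by total 0.5-70 Hz energy (default TRUE).
#' @return Energy (microvolts squared) or relative energy in `[0, 1]`.
#' @export
bandEnergy <- function(spectrum, band = "alpha", relative = TRUE) {
  if (is.character(band)) band <- eegBands()[[match.arg(band, names(eegBands()))]]
  fmax <- max(spectrum$frequency)
  if (band[1] < 0 || band[2] <= band[1] || band[1] > fmax)
    stop("invalid band")
  e <- trapezoidBand(spectrum, band[1], band[2])
  if (relative) {
    tot <- trapezoidBand(spectrum, 0.5, 70)
    if (tot <= 0) return(0)
    e <- e / tot
  }
  e
}

# trapezoidal integral of density over [lo, hi], interpolating the edges
trapezoidBand <- function(spectrum, lo, hi) {
  f <- spectrum$frequency
  d <- spectrum$density
  hi <- min(hi, max(f))
  lo <- max(lo, min(f))
  if (hi <= lo) return(0)
  ff <- sort(unique(c(lo, hi, f[f > lo & f < hi])))
  dd <- stats::approx(f, d, xout = ff)$y
  sum(diff(ff) * (utils::head(dd, -1) + utils::tail(dd, -1)) / 2)
}

#' Relative alpha-band energy of a series
#'
#' Convenience wrapper: [psdWelch()] + [bandEnergy()] over 8-13 Hz.
#'
#' @inheritParams psdWelch
#' @param relative see [bandEnergy()].
#' @return Relative (default) or absolute alpha-band energy.
#' @export
alphaEnergy <- function(x, fs = 256, relative = TRUE) {
  bandEnergy(psdWelch(x, fs), "alpha", relative = relative)
}

#' Per-epoch features for the amplitude-and-Hurst method ("Method One")
#'
#' The two classifier inputs of the first detection method: the mean of the
#' 10 largest per-channel Signal Ranges, and the average over the 19
#' channels of the short-scale AFA Hurst exponent.
#'
#' @param epoch an [EegEpoch-class] with the full 19-channel montage.
#' @param k number of largest ranges averaged (default 10).
#' @param order AFA detrending order (default 2).
#' @return Named numeric vector `c(signal_range =, mean_h =)`.
#' @export
methodOneFeatures <- function(epoch, k = 10L, order = 2) {
  X <- signals(epoch)
  if (nrow(X) != 19L) stop("a full 19-channel epoch is required")
  c(signal_range = topkMeanRange(X, k),
    mean_h = mean(afaHurstMatrix(t(X), order = order)))
}
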