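#' Channel-difference feature network of an epoch
#'
#' Builds the symmetric channels-by-channels matrix whose (i, j) entry is a
#' scalar feature of the difference series `channel_i - channel_j`:
#' the Signal Range, the relative alpha-band energy, or the short-scale AFA
#' Hurst exponent. All three features are invariant under sign flip of the
#' series, so the matrix is computed on the upper triangle and mirrored.
#' The diagonal (a channel minus itself, an identically zero series) is set
#' to 0 by convention for all three features -- the Hurst exponent of a zero
#' series being undefined.
#'
#' @param epoch an [EegEpoch-class]; the full 19-channel montage unless
#'   `strict = FALSE` (toy epochs with fewer channels).
#' @param feature `"signal_range"`, `"alpha_energy"` or `"hurst"`.
#' @param relative for `"alpha_energy"`: relative (default) or absolute.
#' @param order AFA detrending order for `"hurst"`.
#' @param strict require the 19-channel montage (default TRUE).
#' @return A [FeatureNetwork-class].
#' @export
differenceNetwork <- function(epoch,
                              feature = c("signal_range", "alpha_energy",
                                          "hurst"),
                              relative = TRUE, order = 2, strict = TRUE) {
  feature <- match.arg(feature)
  X <- signals(epoch)
  nc <- nrow(X)
  if (strict && nc != 19L)
    stop("a full 19-channel epoch is required (use strict = FALSE for toys)")
  fs <- samplingRate(epoch)
  pairs <- utils::combn(nc, 2L)
  D <- t(X[pairs[1L, ], , drop = FALSE] - X[pairs[2L, ], , drop = FALSE])
  vals <- switch(feature,
    signal_range = colRangeCpp(D),
    alpha_energy = alphaEnergyMatrix(D, fs = fs, relative = relative),
    hurst = afaHurstMatrix(D, order = order))
  A <- matrix(0, nc, nc)
  A[t(pairs)] <- vals
  A <- A + t(A)
  new("FeatureNetwork", matrix = A, feature = feature,
      channelNames = channelNames(epoch))
}

#' Largest singular value and first singular vector
#'
#' Returns the largest singular value of a (feature network) matrix and the
#' corresponding left singular vector, normalised and with its sign fixed
#' so its largest-magnitude entry is positive (making downstream channel
#' selection deterministic).
#'
#' @param network a [FeatureNetwork-class] or plain numeric matrix.
#' @return List with `sigma1` (scalar >= 0) and `u1` (unit vector).
#' @export
firstSingular <- function(network) {
  A <- if (is(network, "FeatureNetwork")) network@matrix else network
  if (!all(is.finite(A))) stop("matrix has non-finite entries")
  s <- svd(A, nu = 1L, nv = 0L)
  u1 <- s$u[, 1L]
  j <- which.max(abs(u1))
  if (u1[j] < 0) u1 <- -u1
  list(sigma1 = s$d[1L], u1 = u1)
}

#' Per-epoch network features ("Method Two")
#'
#' The three classifier inputs of the network-based detection method: the
#' square of the largest singular value of each channel-difference network
#' (Signal Range, relative alpha energy, Hurst), in that fixed order.
#'
#' @inheritParams differenceNetwork
#' @return Named numeric vector
#'   `c(s1sq_range =, s1sq_alpha =, s1sq_hurst =)`.
#' @export
methodTwoFeatures <- function(epoch, relative = TRUE, order = 2) {
  nets <- epochNetworks(epoch, relative = relative, order = order)
  vapply(stats::setNames(nets, c("s1sq_range", "s1sq_alpha", "s1sq_hurst")),
         function(nw) firstSingular(nw)$sigma1^2, numeric(1))
}

#' All three channel-difference networks of an epoch
#'
#' Computes the Signal Range, alpha-energy and Hurst networks in one pass
#' over the channel differences (cheaper than three [differenceNetwork()]
#' calls).
#'
#' @inheritParams differenceNetwork
#' @return Named list of three [FeatureNetwork-class] objects
#'   (`signal_range`, `alpha_energy`, `hurst`).
#' @export
epochNetworks <- function(epoch, relative = TRUE, order = 2, strict = TRUE) {
  X <- signals(epoch)
  nc <- nrow(X)
  if (strict && nc != 19L)
    stop("a full 19-channel epoch is required (use strict = FALSE for toys)")
  fs <- samplingRate(epoch)
  pairs <- utils::combn(nc, 2L)
  D <- t(X[pairs[1L, ], , drop = FALSE] - X[pairs[2L, ], , drop = FALSE])
  mk <- function(vals, feature) {
    A <- matrix(0, nc, nc)
    A[t(pairs)] <- vals
    new("FeatureNetwork", matrix = A + t(A), feature = feature,
        channelNames = channelNames(epoch))
  }
  list(signal_range = mk(colRangeCpp(D), "signal_range"),
       alpha_energy = mk(alphaEnergyMatrix(D, fs = fs, relative = relative),
                         "alpha_energy"),
       hurst = mk(afaHurstMatrix(D, order = order), "hurst"))
}

#' Export a feature network as CSV and heat-map image
#'
#' Writes the matrix (with channel-name row/column headers) to
#' `<path>.csv` and a labelled heat map to `<path>.png`.
#'
#' @param network a [FeatureNetwork-class].
#' @param path output path stem (without extension).
#' @return Invisibly, the two file paths written.
#' @export
exportHeatmap <- function(network, path) {
  m <- networkMatrix(network)
  csv <- paste0(path, ".csv")
  png <- paste0(path, ".png")
  utils::write.csv(m, csv, row.names = TRUE)
  ch <- channelNames(network)
  n <- length(ch)
  grDevices::png(png, width = 640, height = 600)
  op <- graphics::par(mar = c(5, 5, 3, 1))
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, ]), axes = FALSE,
                  xlab = "", ylab = "", main = network@feature,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE))
  graphics::axis(1, at = seq_len(n), labels = ch, las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(ch), las = 2,
                 cex.axis = 0.7)
  graphics::par(op)
  grDevices::dev.off()
  invisible(c(csv, png))
}
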