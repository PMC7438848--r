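#' Random-walk profile of a series
#'
#' Cumulative sum of the mean-removed series,
#' \eqn{u(n) = \sum_{k \le n} (x(k) - \bar x)}; the first step of adaptive
#' fractal analysis. By the telescoping identity the profile ends at zero.
#'
#' @param x numeric series (length >= 2, finite).
#' @return List of class `RandomWalkProfile` with elements `u` (the profile)
#'   and `meanRemoved` (the subtracted mean).
#' @export
randomWalkProfile <- function(x) {
  if (length(x) < 2L) stop("series must have length >= 2")
  stopIfNotFinite(x, "series")
  m <- mean(x)
  structure(list(u = cumsum(x - m), meanRemoved = m),
            class = "RandomWalkProfile")
}

asProfileVector <- function(x) {
  if (inherits(x, "RandomWalkProfile")) x$u else x
}

#' Adaptive global trend of a profile
#'
#' Fits an order-`order` polynomial in each odd-length window of size `w`
#' (adjacent windows overlapping by `(w + 1) / 2` samples) and stitches the
#' fits into one smooth global trend: on each overlap region of length
#' \eqn{n} the two fits \eqn{y^1, y^2} are combined as
#' \eqn{y(l) = (1 - \frac{l-1}{n-1}) y^1(l) + \frac{l-1}{n-1} y^2(l)}.
#' The first and last half-windows take their single covering fit
#' unweighted. Any exact polynomial input of degree `<= order` is
#' reproduced.
#'
#' @param profile a `RandomWalkProfile` or plain numeric series.
#' @param w odd window size, `3 <= w <= length(u)`.
#' @param order polynomial order M, 1 or 2.
#' @return Numeric trend of the same length.
#' @export
globalTrend <- function(profile, w, order = 2) {
  u <- asProfileVector(profile)
  w <- as.integer(w)
  if (w %% 2L == 0L) stop("window size w must be odd")
  if (w < 3L || w > length(u)) stop("w must lie in [3, length(u)]")
  if (!order %in% c(1, 2)) stop("detrending order M must be 1 or 2")
  afaTrendCpp(as.numeric(u), w, as.integer(order))
}

#' Fluctuation function at one window size
#'
#' Root-mean-square residual between the profile and its adaptive global
#' trend: \eqn{F(w) = [\frac{1}{N}\sum_i (u(i) - v(i))^2]^{1/2}}.
#'
#' @inheritParams globalTrend
#' @return `F(w) >= 0`.
#' @export
fluctuation <- function(profile, w, order = 2) {
  u <- asProfileVector(profile)
  v <- globalTrend(u, w, order)
  sqrt(mean((u - v)^2))
}

#' Default AFA window-size grid
#'
#' Window sizes `w = 2^k + 1` for `k = 3..log2(N/4)` merged with the
#' intermediate odd values 11, 25, 49, 97, 193, 385, truncated to
#' `w <= N/2`. The grid starts at `w = 9`: with quadratic detrending, 5- or
#' 7-sample windows leave so few residual degrees of freedom that the
#' fluctuation at those scales is bias-dominated, which systematically
#' inflates the short-scale slope for anti-persistent signals.
#'
#' @param n series length.
#' @return Strictly increasing odd integer vector.
#' @export
afaGrid <- function(n) {
  ks <- 3:max(3, floor(log2(n / 4)))
  w <- sort(unique(c(2^ks + 1, c(11, 25, 49, 97, 193, 385))))
  w <- w[w >= 9 & w <= n / 2]
  as.integer(w)
}

#' AFA scaling curve of a series
#'
#' Computes `log2 F(w)` on the random-walk profile of `x` over a grid of
#' window sizes, giving the log-log scaling curve whose slope estimates the
#' Hurst exponent (`F(w) ~ w^H`). Series shorter than 64 samples are
#' rejected: slope fits over fewer usable scales are unstable.
#'
#' @param x numeric series, length >= 64.
#' @param wGrid odd window sizes (default [afaGrid()] of the length).
#' @param order detrending order M (default 2).
#' @param fit if `TRUE` (default) also run [fitTwoRegimes()].
#' @return A [ScalingCurve-class].
#' @export
#' @examples
#' sc <- scalingCurve(fgnSim(0.7, 2048, seed = 1))
#' hurstShort(sc)
scalingCurve <- function(x, wGrid = NULL, order = 2, fit = TRUE) {
  if (length(x) < 64L) stop("series must have at least 64 samples")
  stopIfNotFinite(x, "series")
  if (is.null(wGrid)) wGrid <- afaGrid(length(x))
  wGrid <- as.integer(wGrid)
  if (!length(wGrid)) stop("empty window-size grid")
  if (any(wGrid < 5L | wGrid > length(x) / 2))
    stop("window sizes must lie in [5, N/2]")
  u <- randomWalkProfile(x)$u
  Fw <- afaFluctCpp(matrix(u, ncol = 1L), wGrid, as.integer(order))[, 1L]
  curve <- new("ScalingCurve", w = as.numeric(wGrid),
               logF = log2(pmax(Fw, .Machine$double.xmin)),
               fitOrder = as.numeric(order))
  if (fit) {
    if (length(wGrid) >= 6L) {
      curve <- fitTwoRegimes(curve)
    } else {
      # too few scales to resolve two regimes: one global line
      sl <- unname(stats::lm.fit(cbind(1, log2(curve@w)),
                                 curve@logF)$coefficients[2])
      curve@hShort <- sl
      curve@hLong <- sl
    }
  }
  curve
}

#' Two-regime fit of a scaling curve
#'
#' Splits the (log2 w, log2 F) points into a short-scale and a long-scale
#' segment at the breakpoint minimising the total squared error of two
#' independent least-squares lines, with at least 3 points per segment.
#' The short-scale slope is the Hurst estimate used throughout the package.
#'
#' @param curve a [ScalingCurve-class] with at least 6 points.
#' @return The curve with `hShort`, `hLong` and `breakpoint` filled in.
#' @export
fitTwoRegimes <- function(curve) {
  best <- twoSegmentFit(log2(curve@w), curve@logF)
  curve@hShort <- best$h1
  curve@hLong <- best$h2
  curve@breakpoint <- best$b
  curve
}

# breakpoint b = last point of the short-scale segment; two independent OLS
# lines on points 1..b and (b+1)..K, >= 3 points each; first SSE minimum wins
twoSegmentFit <- function(lw, lf) {
  K <- length(lw)
  if (K < 6L) stop("two-regime fit needs at least 6 grid points")
  segFit <- function(i) {
    f <- stats::lm.fit(cbind(1, lw[i]), lf[i])
    list(slope = unname(f$coefficients[2]), sse = sum(f$residuals^2))
  }
  best <- NULL
  for (b in 3:(K - 3)) {
    f1 <- segFit(1:b)
    f2 <- segFit((b + 1):K)
    sse <- f1$sse + f2$sse
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(b = b, sse = sse, h1 = f1$slope, h2 = f2$slope)
  }
  best
}

#' Short-scale Hurst exponent of a series via AFA
#'
#' Convenience wrapper: [scalingCurve()] + [fitTwoRegimes()], returning the
#' short-scale slope.
#'
#' @inheritParams scalingCurve
#' @return Numeric Hurst estimate.
#' @export
afaHurst <- function(x, wGrid = NULL, order = 2) {
  hurstShort(scalingCurve(x, wGrid = wGrid, order = order, fit = TRUE))
}

#' Short-scale Hurst exponents for many series at once
#'
#' Batch interface over the columns of a matrix (used for the 19 channels
#' of an epoch and the 171 channel-difference series of a network); much
#' faster than calling [afaHurst()] per column.
#'
#' @param X numeric matrix, one series per column (nrow >= 64).
#' @param wGrid,order as in [scalingCurve()].
#' @return Numeric vector of `ncol(X)` short-scale Hurst estimates.
#' @export
afaHurstMatrix <- function(X, wGrid = NULL, order = 2) {
  n <- nrow(X)
  if (n < 64L) stop("series must have at least 64 samples")
  if (is.null(wGrid)) wGrid <- afaGrid(n)
  wGrid <- as.integer(wGrid)
  Fw <- afaFluctCpp(X, wGrid, as.integer(order), profile = TRUE)
  lw <- log2(as.numeric(wGrid))
  lf <- log2(pmax(Fw, .Machine$double.xmin))   # G x S
  if (length(lw) >= 6L) twoSegmentFitMatrix(lw, lf)
  else apply(lf, 2, function(y)
    unname(stats::lm.fit(cbind(1, lw), y)$coefficients[2]))
}

# vectorised twoSegmentFit over the columns of lf (G x S): returns the
# short-segment slope per column; agrees with twoSegmentFit per column
twoSegmentFitMatrix <- function(lw, lf) {
  G <- length(lw)
  S <- ncol(lf)
  cl <- cumsum(lw)
  cl2 <- cumsum(lw^2)
  S1 <- apply(lf, 2, cumsum)
  S2 <- apply(lf^2, 2, cumsum)
  Sx <- apply(lw * lf, 2, cumsum)
  bestSse <- rep(Inf, S)
  bestH1 <- rep(NA_real_, S)
  for (b in 3:(G - 3)) {
    n1 <- b
    sxx1 <- cl2[b] - cl[b]^2 / n1
    sl1 <- (Sx[b, ] - cl[b] * S1[b, ] / n1) / sxx1
    sse1 <- (S2[b, ] - S1[b, ]^2 / n1) - sl1^2 * sxx1
    n2 <- G - b
    sx <- cl[G] - cl[b]
    sxx2 <- (cl2[G] - cl2[b]) - sx^2 / n2
    sy <- S1[G, ] - S1[b, ]
    sl2 <- ((Sx[G, ] - Sx[b, ]) - sx * sy / n2) / sxx2
    sse2 <- ((S2[G, ] - S2[b, ]) - sy^2 / n2) - sl2^2 * sxx2
    sse <- sse1 + sse2
    upd <- sse < bestSse - 1e-12
    bestSse[upd] <- sse[upd]
    bestH1[upd] <- sl1[upd]
  }
  bestH1
}
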