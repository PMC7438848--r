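# Independent reference implementations used as oracles.

# Plain-R AFA global trend: overlapped windows of odd size w (step
# (w-1)/2, final window pinned to end at N), per-window polynomial fit of
# order M, linear crossfade over each overlap. Written directly from the
# stitching rule, independently of the compiled implementation.
refGlobalTrend <- function(u, w, order) {
  N <- length(u)
  step <- (w - 1) %/% 2
  starts <- seq(1, N - w + 1, by = step)
  if (starts[length(starts)] != N - w + 1) starts <- c(starts, N - w + 1)
  v <- rep(NA_real_, N)
  prevEnd <- 0
  for (s in starts) {
    idx <- s:(s + w - 1)
    fit <- stats::lm(y ~ poly(x, order, raw = TRUE),
                     data = data.frame(x = seq_len(w), y = u[idx]))
    yhat <- unname(stats::fitted(fit))
    if (prevEnd == 0) {
      v[idx] <- yhat
    } else {
      o <- prevEnd - s + 1
      l <- seq_len(o)
      t <- if (o > 1) (l - 1) / (o - 1) else 1
      v[s + l - 1] <- (1 - t) * v[s + l - 1] + t * yhat[l]
      if (o < w) v[(s + o):(s + w - 1)] <- yhat[(o + 1):w]
    }
    prevEnd <- s + w - 1
  }
  v
}

# quiet, jitter-free generator settings used by several planted-effect tests
quietConfig <- function(...) {
  synthConfig(subjectGainSdlog = 0, channelGainSdlog = 0,
              badChannelProb = 0, hSd = 0, ...)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
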