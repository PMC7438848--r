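#' Exact fractional Gaussian noise by circulant embedding
#'
#' Simulates stationary fractional Gaussian noise (fGn) with Hurst exponent
#' `h` and standard deviation `sd` using circulant embedding (Davies-Harte),
#' which reproduces the fGn autocovariance
#' \deqn{\gamma(k) = \frac{sd^2}{2}\left(|k+1|^{2h} - 2|k|^{2h} +
#'   |k-1|^{2h}\right)}
#' exactly (up to floating point), so simulated series carry a known true
#' Hurst exponent for validating estimators. `h = 0.5` gives white noise;
#' `h > 0.5` persistent, `h < 0.5` anti-persistent noise.
#'
#' @param h Hurst exponent, strictly in (0, 1).
#' @param n series length (>= 2).
#' @param sd marginal standard deviation (default 1).
#' @param seed optional integer; the same seed yields the same series and
#'   the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- fgnSim(0.8, 1024, seed = 1)
fgnSim <- function(h, n, sd = 1, seed = NULL) {
  stopifnot(length(h) == 1L, is.finite(h))
  if (h <= 0 || h >= 1) stop("h must lie strictly in (0, 1)")
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be an integer >= 2")
  m <- 2^ceiling(log2(n))
  g <- fgnAutocov(h, 0:m, sd = sd)
  cc <- c(g, g[m:2])                       # circulant first row, length 2m
  lam <- Re(stats::fft(cc))
  lam[lam < 0 & lam > -1e-8 * max(lam)] <- 0
  if (any(lam < 0)) stop("circulant embedding not nonnegative definite")
  withSeed(seed, {
    m2 <- 2L * m
    z <- stats::rnorm(m2)
    w <- complex(length.out = m2)
    w[1] <- sqrt(lam[1]) * z[1]
    w[m + 1] <- sqrt(lam[m + 1]) * z[2]
    k <- 2:m
    a <- z[2 * k - 1]
    b <- z[2 * k]
    w[k] <- sqrt(lam[k] / 2) * complex(real = a, imaginary = b)
    w[m2 + 2 - k] <- Conj(w[k])
    x <- Re(stats::fft(w)) / sqrt(m2)
    x[seq_len(n)]
  })
}

#' Theoretical fGn autocovariance
#'
#' @param h Hurst exponent in (0, 1).
#' @param k lag(s), non-negative integers.
#' @param sd marginal standard deviation.
#' @return Autocovariance at the requested lags.
#' @export
fgnAutocov <- function(h, k, sd = 1) {
  k <- abs(k)
  (sd^2 / 2) * (abs(k + 1)^(2 * h) - 2 * k^(2 * h) + abs(k - 1)^(2 * h))
}

#' Synthetic EEG generator configuration
#'
#' Bundles the parameters of the synthetic 19-channel EEG generator. The
#' defaults define the package's reference study conditions: fractal
#' background with class-dependent Hurst exponent, an alpha rhythm that is
#' stronger in the discharge class and occipitally dominant, and discharge
#' templates planted on a focal channel subset with spatial attenuation.
#'
#' @param nChannels number of channels (19; the full 10-20 montage).
#' @param fs sampling rate, Hz.
#' @param epochLen epoch length, seconds.
#' @param hNormal,hDischarge background Hurst exponents for the two classes,
#'   in (0, 1).
#' @param hSd per-epoch standard deviation of the background Hurst exponent
#'   (biological epoch-to-epoch variability; draws are clipped to
#'   [0.05, 0.95]).
#' @param bgSd background fGn standard deviation, microvolts.
#' @param alphaAmpNormal,alphaAmpDischarge alpha rhythm (8-13 Hz) amplitude
#'   per class, microvolts; doubled on O1/O2 to emulate occipital dominance.
#' @param alphaJitterSdlog sdlog of the lognormal per-epoch alpha amplitude
#'   jitter.
#' @param subjectGainSdlog sdlog of the lognormal per-epoch (subject-level)
#'   gain applied to the whole epoch.
#' @param channelGainSdlog sdlog of the lognormal per-channel gain
#'   (electrode contact/impedance variability), applied to each channel's
#'   full signal. Together the two gains make discharge and normal epochs
#'   overlap in amplitude, as clinical recordings do.
#' @param focalChannels channel names that receive planted discharges, or
#'   `NULL` to draw a fresh random focal set for each discharge epoch.
#' @param focalSizeRange `c(min, max)` number of focal channels drawn per
#'   epoch when `focalChannels` is `NULL`.
#' @param attenuation per-hop amplitude decay factor in (0, 1] applied to a
#'   planted template on 10-20 neighbours of the focal set.
#' @param ampJitter relative amplitude jitter (sd) applied independently per
#'   receiving channel, so that a discharge never cancels exactly in a
#'   channel difference.
#' @param onsetJitterMs onset jitter per channel, +- milliseconds.
#' @param badChannelProb probability that an epoch contains one
#'   noise-contaminated electrode (poor contact), in either class.
#' @param badChannelNoiseSd `c(lo, hi)` range of the white-noise standard
#'   deviation (microvolts) added to a contaminated electrode.
#' @param polarity template polarity, -1 (negative-going, the usual clinical
#'   convention for sharp transients) or +1.
#' @return A list of class `SynthConfig`.
#' @export
synthConfig <- function(nChannels = 19L, fs = 256, epochLen = 4,
                        hNormal = 0.60, hDischarge = 0.45, hSd = 0.08,
                        bgSd = 15, alphaAmpNormal = 10,
                        alphaAmpDischarge = 30, alphaJitterSdlog = 0.3,
                        subjectGainSdlog = 0.15, channelGainSdlog = 0.4,
                        focalChannels = NULL, focalSizeRange = c(2L, 5L),
                        attenuation = 0.5,
                        ampJitter = 0.2, onsetJitterMs = 10,
                        badChannelProb = 0.2,
                        badChannelNoiseSd = c(20, 60),
                        polarity = -1) {
  stopifnot(nChannels == 19L,
            fs > 0, epochLen > 0, abs(fs * epochLen - round(fs * epochLen)) < 1e-9,
            hNormal > 0, hNormal < 1, hDischarge > 0, hDischarge < 1,
            bgSd >= 0, alphaAmpNormal >= 0, alphaAmpDischarge >= 0,
            attenuation > 0, attenuation <= 1, polarity %in% c(-1, 1))
  if (!is.null(focalChannels))
    stopifnot(all(focalChannels %in% tenTwentyChannels()))
  structure(list(nChannels = 19L, fs = fs, epochLen = epochLen,
                 hNormal = hNormal, hDischarge = hDischarge, hSd = hSd,
                 bgSd = bgSd, alphaAmpNormal = alphaAmpNormal,
                 alphaAmpDischarge = alphaAmpDischarge,
                 alphaJitterSdlog = alphaJitterSdlog,
                 subjectGainSdlog = subjectGainSdlog,
                 channelGainSdlog = channelGainSdlog,
                 focalChannels = focalChannels,
                 focalSizeRange = focalSizeRange, attenuation = attenuation,
                 ampJitter = ampJitter, onsetJitterMs = onsetJitterMs,
                 badChannelProb = badChannelProb,
                 badChannelNoiseSd = badChannelNoiseSd,
                 polarity = polarity),
            class = "SynthConfig")
}

templateRanges <- function() {
  list(
    spike          = list(durationMs = c(20, 70),   amplitude = c(50, Inf)),
    sharp          = list(durationMs = c(70, 200),  amplitude = c(100, 200)),
    spike_slow     = list(durationMs = c(20, 70),   amplitude = c(50, Inf)),
    sharp_slow     = list(durationMs = c(70, 200),  amplitude = c(100, 200)),
    polyspike      = list(durationMs = c(20, 70),   amplitude = c(50, Inf)),
    polyspike_slow = list(durationMs = c(20, 70),   amplitude = c(50, Inf)),
    spike_rhythm   = list(durationMs = c(1000, Inf), amplitude = c(100, 200))
  )
}

# Smooth asymmetric transient: half-cosine rise to the peak at fraction
# `peakAt` of the duration, half-cosine fall back to baseline. Range
# (max - min) is exactly 1.
transientShape <- function(nSamples, peakAt = 0.35) {
  t <- seq(0, 1, length.out = nSamples)
  ifelse(t < peakAt,
         (1 - cos(pi * t / peakAt)) / 2,
         (1 + cos(pi * (t - peakAt) / (1 - peakAt))) / 2)
}

halfSine <- function(nSamples) sin(pi * seq(0, 1, length.out = nSamples))

#' Build an epileptiform discharge waveform template
#'
#' Returns one of the seven canonical discharge waveforms at sampling rate
#' `fs`, with parameters constrained to the clinical definition of each
#' type: spikes last 20-70 ms with amplitude above 50 uV; sharp waves last
#' 70-200 ms at 100-200 uV; the slow-wave complexes append a 200-500 ms
#' half-sine slow wave; a polyspike contains two or more consecutive spikes;
#' a spike rhythm is a 10-25 Hz spike train of at least 1 s at 100-200 uV.
#' Defaults are range midpoints (spike amplitude defaults to 150 uV, the
#' upper range being open-ended).
#'
#' @param kind one of [dischargeTypes()].
#' @param fs sampling rate, Hz.
#' @param durationMs transient duration, ms (spike/sharp component; for
#'   `spike_rhythm` the total duration, >= 1000).
#' @param amplitude peak-to-trough amplitude, microvolts.
#' @param slowMs slow-wave duration for the *_slow complexes, ms (200-500).
#' @param slowAmplitude slow-wave amplitude, microvolts (defaults to
#'   `0.8 * amplitude`).
#' @param nSpikes number of spikes in a polyspike complex (>= 2).
#' @param freq spike-rhythm repetition frequency, Hz (10-25).
#' @param polarity -1 or +1.
#' @return A list of class `DischargeTemplate` with elements `kind`,
#'   `durationMs`, `amplitude`, `fs` and `waveform` (numeric vector).
#' @export
#' @examples
#' tpl <- makeTemplate("spike", durationMs = 40, amplitude = 100)
#' length(tpl$waveform)  # round(40 * 256 / 1000) = 10 samples
makeTemplate <- function(kind, fs = 256, durationMs = NULL, amplitude = NULL,
                         slowMs = 350, slowAmplitude = NULL, nSpikes = 3L,
                         freq = 15, polarity = -1) {
  kind <- match.arg(kind, dischargeTypes())
  rng <- templateRanges()[[kind]]
  if (is.null(durationMs))
    durationMs <- if (kind == "spike_rhythm") 1500 else
      mean(pmin(rng$durationMs, 200))
  if (is.null(amplitude))
    amplitude <- if (is.finite(rng$amplitude[2]))
      mean(rng$amplitude) else 150
  if (durationMs < rng$durationMs[1] || durationMs > rng$durationMs[2])
    stop(sprintf("%s duration must lie in [%g, %g] ms", kind,
                 rng$durationMs[1], rng$durationMs[2]))
  if (amplitude < rng$amplitude[1] || amplitude > rng$amplitude[2])
    stop(sprintf("%s amplitude must lie in [%g, %g] uV", kind,
                 rng$amplitude[1], rng$amplitude[2]))
  stopifnot(polarity %in% c(-1, 1))
  nOf <- function(ms) max(2L, as.integer(round(ms * fs / 1000)))
  if (is.null(slowAmplitude)) slowAmplitude <- 0.8 * amplitude

  wave <- switch(kind,
    spike = ,
    sharp = amplitude * transientShape(nOf(durationMs)),
    spike_slow = ,
    sharp_slow = {
      if (slowMs < 200 || slowMs > 500)
        stop("slow-wave duration must lie in [200, 500] ms")
      c(amplitude * transientShape(nOf(durationMs)),
        slowAmplitude * halfSine(nOf(slowMs)))
    },
    polyspike = ,
    polyspike_slow = {
      nSpikes <- as.integer(nSpikes)
      if (is.na(nSpikes) || nSpikes < 2L)
        stop("a polyspike complex requires two or more spikes")
      w <- rep(amplitude * transientShape(nOf(durationMs)), nSpikes)
      if (kind == "polyspike_slow") {
        if (slowMs < 200 || slowMs > 500)
          stop("slow-wave duration must lie in [200, 500] ms")
        w <- c(w, slowAmplitude * halfSine(nOf(slowMs)))
      }
      w
    },
    spike_rhythm = {
      if (freq < 10 || freq > 25)
        stop("spike rhythm frequency must lie in [10, 25] Hz")
      # train of narrow transients repeating at `freq`: harmonically rich
      # but with its fundamental, hence the dominant PSD peak, at `freq`
      amplitude * spikeTrain(nOf(durationMs), fs, freq)
    })
  wave <- polarity * wave
  structure(list(kind = kind, durationMs = durationMs, amplitude = amplitude,
                 fs = fs, waveform = wave),
            class = "DischargeTemplate")
}

# Periodic spiky waveform with unit range and fundamental at `freq`.
spikeTrain <- function(n, fs, freq) {
  u <- ((seq_len(n) - 1) / fs * freq) %% 1   # phase in [0,1)
  # 60% duty keeps each pulse spike-like while the fundamental (not the
  # second harmonic) carries the most power
  duty <- 0.6
  s <- ifelse(u < duty, transientShapeAt(u / duty), 0)
  s
}

transientShapeAt <- function(t, peakAt = 0.35) {
  ifelse(t < peakAt,
         (1 - cos(pi * t / peakAt)) / 2,
         (1 + cos(pi * (t - peakAt) / (1 - peakAt))) / 2)
}

#' Generate one synthetic labeled EEG epoch
#'
#' Composes, per channel, fGn background at the class's Hurst exponent, an
#' alpha-band sinusoid with random phase (class-dependent amplitude, doubled
#' on O1/O2), and -- for discharge labels -- the corresponding template
#' planted on the focal channels with independent per-channel amplitude and
#' onset jitter, attenuated by `attenuation^d` on channels at 10-20 graph
#' distance `d` from the focal set.
#'
#' @param label `"normal"` or one of [dischargeTypes()].
#' @param config a [synthConfig()] list.
#' @param seed optional integer seed (epoch is fully reproducible given it).
#' @param templateArgs optional list of extra arguments to [makeTemplate()].
#' @return An [EegEpoch-class] with the label and ground-truth focal set.
#' @export
#' @examples
#' ep <- genEpoch("spike", synthConfig(focalChannels = c("F7", "T3")), seed = 1)
genEpoch <- function(label, config = synthConfig(), seed = NULL,
                     templateArgs = list()) {
  stopifnot(inherits(config, "SynthConfig"))
  label <- match.arg(label, c("normal", dischargeTypes()))
  ch <- tenTwentyChannels()
  n <- as.integer(round(config$fs * config$epochLen))
  withSeed(seed, {
    isDischarge <- label != "normal"
    hMean <- if (isDischarge) config$hDischarge else config$hNormal
    h <- min(0.95, max(0.05, stats::rnorm(1, hMean, config$hSd)))
    X <- matrix(0, 19L, n, dimnames = list(ch, NULL))
    for (i in seq_len(19L))
      X[i, ] <- fgnSim(h, n, sd = config$bgSd)
    aAmp <- (if (isDischarge) config$alphaAmpDischarge else
               config$alphaAmpNormal) *
      stats::rlnorm(1, 0, config$alphaJitterSdlog)
    aFreq <- stats::runif(1, 8, 13)
    tt <- (seq_len(n) - 1) / config$fs
    occ <- ifelse(ch %in% c("O1", "O2"), 2, 1)
    for (i in seq_len(19L))
      X[i, ] <- X[i, ] + occ[i] * aAmp * sin(2 * pi * aFreq * tt +
                                             stats::runif(1, 0, 2 * pi))
    focal <- character(0)
    if (isDischarge) {
      focal <- config$focalChannels
      if (is.null(focal))
        focal <- sample(ch, sample(seq(config$focalSizeRange[1],
                                       config$focalSizeRange[2]), 1L))
      if (is.null(templateArgs$amplitude))
        templateArgs$amplitude <- sampleTemplateAmplitude(label)
      tpl <- do.call(makeTemplate,
                     c(list(kind = label, fs = config$fs,
                            polarity = config$polarity), templateArgs))
      d <- channelDistance(focal)
      gain <- config$attenuation^d
      gain[gain < 0.05] <- 0               # negligible beyond ~4 hops
      L <- length(tpl$waveform)
      if (L >= n) stop("template longer than the epoch")
      onset0 <- sample.int(n - L - as.integer(config$fs * 0.05), 1) +
        as.integer(config$fs * 0.02)
      jitN <- as.integer(round(config$onsetJitterMs * config$fs / 1000))
      for (i in seq_len(19L)) {
        if (gain[i] == 0) next
        o <- onset0 + if (jitN > 0) sample(seq(-jitN, jitN), 1) else 0L
        o <- min(max(1L, o), n - L)
        a <- gain[i] * (1 + stats::rnorm(1, 0, config$ampJitter))
        X[i, o:(o + L - 1L)] <- X[i, o:(o + L - 1L)] + a * tpl$waveform
      }
    }
    if (stats::runif(1) < config$badChannelProb) {
      bad <- sample.int(19L, 1L)
      X[bad, ] <- X[bad, ] + stats::rnorm(n, 0,
        stats::runif(1, config$badChannelNoiseSd[1],
                     config$badChannelNoiseSd[2]))
    }
    gain <- stats::rlnorm(1, 0, config$subjectGainSdlog) *
      stats::rlnorm(19L, 0, config$channelGainSdlog)
    X <- X * gain
    EegEpoch(X, fs = config$fs, label = label, focalChannels = focal)
  })
}

# Clinical amplitudes vary widely epoch to epoch; draw uniformly from each
# type's plausible range (spike family is open-ended above 50 uV).
sampleTemplateAmplitude <- function(kind) {
  if (kind %in% c("spike", "spike_slow", "polyspike", "polyspike_slow"))
    stats::runif(1, 60, 250)
  else stats::runif(1, 100, 200)
}

#' Generate a labeled synthetic dataset
#'
#' Produces `nNormal` normal epochs plus `nPerType[k]` epochs of each
#' discharge type, in seed-deterministic shuffled order. The default type
#' counts are the clinical catalog [defaultTypeCounts()] (540 discharge
#' epochs) with 100 normals, i.e. 640 epochs in total.
#'
#' @param nNormal number of normal epochs.
#' @param nPerType named or positional integer vector over
#'   [dischargeTypes()].
#' @param config a [synthConfig()].
#' @param seed integer master seed.
#' @return List of [EegEpoch-class] objects.
#' @export
genDataset <- function(nNormal = 100L, nPerType = defaultTypeCounts(),
                       config = synthConfig(), seed = NULL) {
  stopifnot(nNormal >= 0, all(nPerType >= 0),
            length(nPerType) == length(dischargeTypes()))
  if (is.null(names(nPerType))) names(nPerType) <- dischargeTypes()
  labels <- c(rep("normal", nNormal),
              rep(names(nPerType), times = as.integer(nPerType)))
  if (!length(labels)) return(list())
  withSeed(seed, {
    labels <- sample(labels)
    seeds <- deriveSeeds(if (is.null(seed)) stats::runif(1, 1, 2^30) else seed,
                         length(labels))
    lapply(seq_along(labels), function(i)
      genEpoch(labels[i], config, seed = seeds[i]))
  })
}
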