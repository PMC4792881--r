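#' Preset Markov chain for a Light-period-like recording
#'
#' Diagonal-dominant transition matrix whose stationary distribution is
#' close to the Wake/NREM/REM proportions typical of the mouse Light
#' (rest) period, about 35/55/10 percent. Dwell times are geometric with
#' means of roughly 85 s (Wake), 108 s (NREM) and 39 s (REM) at 4-s epochs.
#'
#' @return A [VigilanceChain-class].
#' @export
lightChain <- function() {
  A <- matrix(c(0.953, 0.045, 0.002,
                0.019, 0.963, 0.018,
                0.062, 0.040, 0.898), 3, 3, byrow = TRUE)
  vigilanceChain(A)
}

#' Preset Markov chain for a Dark-period-like recording
#'
#' Mice are nocturnally active: the Dark-period preset spends about 72% of
#' time awake, 27% in NREM and under 2% in REM, exercising the REM-scarcity
#' regime in which unsupervised models see too few REM epochs to estimate
#' its distribution well.
#'
#' @return A [VigilanceChain-class].
#' @export
darkChain <- function() {
  A <- matrix(c(0.975, 0.024, 0.001,
                0.060, 0.930, 0.010,
                0.120, 0.080, 0.800), 3, 3, byrow = TRUE)
  vigilanceChain(A)
}

#' Preset per-state feature distributions
#'
#' Gaussian state-conditional distributions of the smoothed-log feature
#' triplet emulating the cluster geometry of real recordings: WAKE sits
#' high on the EMG axis; NREM low on EMG and high on delta/theta; REM low
#' on EMG, low on delta/theta and raised on the high/low ratio. With the
#' default `noiseScale = 1` the state means are separated by roughly 8.6
#' standard deviations on their discriminating axes, giving clusters that
#' are clearly separable yet overlapping in their tails; larger values
#' shrink the separation proportionally.
#'
#' @param noiseScale multiplier applied to all standard deviations
#'   (default 1).
#' @return A [StateFeatureModel-class].
#' @export
defaultStateFeatureModel <- function(noiseScale = 1) {
  stopifnot(noiseScale > 0)
  means <- matrix(c( 2.0,  0.0,  0.0,    # WAKE: high muscle tone
                    -1.0,  1.5, -1.5,    # NREM: delta-dominant EEG
                    -1.0, -1.5,  0.5),   # REM: theta-dominant, raised hi/lo
                  3, 3, byrow = TRUE,
                  dimnames = list(c("WAKE", "NREM", "REM"),
                                  c("emg_rms", "dt_ratio", "hl_ratio")))
  sds <- matrix(0.35 * noiseScale, 3, 3, dimnames = dimnames(means))
  new("StateFeatureModel", means = means, sds = sds)
}

#' Simulate a hypnogram from a Markov chain
#'
#' @param chain a [VigilanceChain-class].
#' @param T number of epochs.
#' @param seed integer RNG seed.
#' @param epochS epoch duration (default 4 s).
#' @return A [Hypnogram-class].
#' @examples
#' h <- simulateHypnogram(lightChain(), T = 100, seed = 1)
#' sleepMetrics(h)
#' @export
simulateHypnogram <- function(chain, T, seed = 0, epochS = 4) {
  stopifnot(is(chain, "VigilanceChain"), T >= 1)
  T <- as.integer(T)
  withSeed(seed, {
    states <- integer(T)
    states[1] <- sample.int(3L, 1L, prob = chain@pi)
    if (T > 1L) for (t in 2:T)
      states[t] <- sample.int(3L, 1L, prob = chain@A[states[t - 1L], ])
    hypnogram(c("WAKE", "NREM", "REM")[states], epochS = epochS)
  })
}

#' Simulate smoothed-log features for a hypnogram
#'
#' Draws each epoch's feature triplet from the Gaussian distribution of its
#' vigilance state (diagonal covariance).
#'
#' @param h a [Hypnogram-class] of ground-truth states.
#' @param sfm a [StateFeatureModel-class]
#'   (default [defaultStateFeatureModel()]).
#' @param seed integer RNG seed.
#' @return A [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @export
simulateFeatures <- function(h, sfm = defaultStateFeatureModel(), seed = 0) {
  stopifnot(is(h, "Hypnogram"), is(sfm, "StateFeatureModel"))
  si <- match(h@labels, c("WAKE", "NREM", "REM"))
  T <- length(si)
  withSeed(seed, {
    draws <- matrix(stats::rnorm(3 * T), T, 3)
    m <- sfm@means[si, , drop = FALSE] + draws * sfm@sds[si, , drop = FALSE]
    featureSeries(emgRMS = m[, 1], dtRatio = m[, 2], hlRatio = m[, 3],
                  epochS = h@epochS, stage = "smoothed_log")
  })
}

#' Simulate a raw EEG/EMG recording for a hypnogram
#'
#' Generates state-conditioned signals realizing the spectral contrasts the
#' feature extractor measures: the EEG is a sinusoid whose frequency and
#' amplitude depend on the state (NREM: 2 Hz, amplitude 3, inside the delta
#' band; REM: 7 Hz, amplitude 2, inside the theta band; WAKE: 12 Hz,
#' amplitude 1) plus white noise (sd 0.5); the EMG is white noise
#' band-limited to 10-100 Hz with state-dependent amplitude (WAKE 2.0,
#' NREM/REM 0.3). The sinusoid phase is continuous across epochs.
#'
#' @param h a [Hypnogram-class].
#' @param fs sampling rate in Hz (>= 200; default 400).
#' @param seed integer RNG seed.
#' @return A [SignalRecording-class] of `nEpochs(h) * epochS * fs` samples.
#' @export
simulateRaw <- function(h, fs = 400, seed = 0) {
  stopifnot(is(h, "Hypnogram"))
  if (fs < 200) stop("fs must be at least 200 Hz")
  spe <- h@epochS * fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epochS * fs must be a whole number of samples")
  spe <- as.integer(round(spe))
  si <- match(h@labels, c("WAKE", "NREM", "REM"))
  T <- length(si)
  n <- T * spe

  eegFreq <- c(12, 2, 7)[si]
  eegAmp <- c(1, 3, 2)[si]
  emgAmp <- c(2.0, 0.3, 0.3)[si]
  freqS <- rep(eegFreq, each = spe)
  ampS <- rep(eegAmp, each = spe)
  emgS <- rep(emgAmp, each = spe)

  # integrate frequency for phase continuity across state changes
  phase <- 2 * pi * cumsum(freqS) / fs
  withSeed(seed, {
    eeg <- ampS * sin(phase) + stats::rnorm(n, sd = 0.5)
    emgNoise <- stats::rnorm(n, sd = 1) * emgS
    emg <- bandpass(emgNoise, fs, 10, min(100, fs / 2 - 1), order = 3)
    signalRecording(eeg, emg, fs = fs, startTime = 0)
  })
}

#' Simulate a multi-subject cohort
#'
#' Generates per-subject (hypnogram, features) pairs whose generators are
#' jittered around the presets: every entry of the transition matrix, state
#' mean and state standard deviation is multiplied by an independent
#' `1 + U(-jitter, jitter)` draw (transition rows renormalized), emulating
#' inter-animal variability. With `jitter = 0` all subjects share identical
#' generators.
#'
#' @param nSubjects number of subjects (default 18, a typical cohort size).
#' @param T epochs per subject (default 12600, i.e. 14 h of 4-s epochs).
#' @param seeds integer vector of per-subject seeds, length >= `nSubjects`.
#' @param jitter multiplicative jitter half-width (default 0.05).
#' @param chain base [VigilanceChain-class] (default [lightChain()]).
#' @param sfm base [StateFeatureModel-class].
#' @param epochS epoch duration (default 4 s).
#' @return list of length `nSubjects`; each element a list with `hypnogram`,
#'   `features`, `chain` and `sfm` (the subject's jittered generators).
#' @export
simulateCohort <- function(nSubjects = 18, T = 12600,
                           seeds = seq_len(nSubjects), jitter = 0.05,
                           chain = lightChain(),
                           sfm = defaultStateFeatureModel(), epochS = 4) {
  stopifnot(nSubjects >= 1)
  if (length(seeds) < nSubjects)
    stop("seed list shorter than the number of subjects")
  lapply(seq_len(nSubjects), function(s) {
    seed <- as.integer(seeds[s])
    subj <- withSeed(seed * 1000L + 1L, {
      jit <- function(x) x * (1 + stats::runif(length(x), -jitter, jitter))
      A <- matrix(jit(chain@A), 3, 3, dimnames = dimnames(chain@A))
      A <- A / rowSums(A)
      means <- matrix(jit(sfm@means), 3, 3, dimnames = dimnames(sfm@means))
      sds <- matrix(jit(sfm@sds), 3, 3, dimnames = dimnames(sfm@sds))
      list(chain = vigilanceChain(A),
           sfm = new("StateFeatureModel", means = means, sds = sds))
    })
    h <- simulateHypnogram(subj$chain, T, seed = seed * 1000L + 2L,
                           epochS = epochS)
    f <- simulateFeatures(h, subj$sfm, seed = seed * 1000L + 3L)
    list(hypnogram = h, features = f, chain = subj$chain, sfm = subj$sfm)
  })
}
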