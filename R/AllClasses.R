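#' @import methods
NULL

#' Canonical vigilance-state order
#'
#' All hypnograms, transition matrices and emission matrices in this package
#' index the three vigilance states in this fixed order. Ties in
#' nearest-centroid assignment and Viterbi decoding are broken toward the
#' state that appears earlier in this vector.
#'
#' @return `c("WAKE", "NREM", "REM")`
#' @export
vigilanceStates <- function() c("WAKE", "NREM", "REM")

.STATES <- c("WAKE", "NREM", "REM")

#' SignalRecording: synchronized EEG/EMG sample streams
#'
#' Container for a two-channel electrophysiological recording: one epidural
#' EEG channel and one nuchal EMG channel sampled at a common rate.
#'
#' @slot eeg numeric vector of EEG samples (microvolts).
#' @slot emg numeric vector of EMG samples (microvolts); same length as `eeg`.
#' @slot fs sampling rate in Hz.
#' @slot startTime recording start offset in seconds (0 allowed).
#' @export
setClass("SignalRecording",
  representation(eeg = "numeric", emg = "numeric", fs = "numeric",
                 startTime = "numeric"),
  prototype(startTime = 0)
)

setValidity("SignalRecording", function(object) {
  if (length(object@eeg) != length(object@emg))
    return("eeg and emg must have equal length")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    return("fs must be a single positive number")
  if (!all(is.finite(object@eeg)) || !all(is.finite(object@emg)))
    return("signal samples must be finite")
  TRUE
})

#' Construct a SignalRecording
#'
#' @param eeg numeric EEG samples (microvolts).
#' @param emg numeric EMG samples (microvolts), same length as `eeg`.
#' @param fs sampling rate (Hz).
#' @param startTime start offset in seconds.
#' @return A [SignalRecording-class] object.
#' @examples
#' rec <- signalRecording(rnorm(4000), rnorm(4000), fs = 400)
#' rec
#' @export
signalRecording <- function(eeg, emg, fs, startTime = 0) {
  new("SignalRecording", eeg = as.numeric(eeg), emg = as.numeric(emg),
      fs = as.numeric(fs), startTime = as.numeric(startTime))
}

#' FeatureConfig: feature-extraction parameters
#'
#' Frequency bands, epoch length, filter order and smoothing window used to
#' turn raw EEG/EMG signals into per-epoch features. Defaults follow standard
#' practice for mouse sleep recordings sampled at 400 Hz: 4-s epochs, a
#' 3rd-order Butterworth filter per band, and a 4-epoch (16 s) moving average.
#'
#' @slot epochS epoch duration in seconds.
#' @slot emgBand EMG muscle-tone band (Hz), default 80-100.
#' @slot deltaBand EEG delta band (Hz), default 0.5-4.
#' @slot thetaBand EEG theta band (Hz), default 6-9.
#' @slot hiBand EEG high band (Hz), default 9-45.
#' @slot loBand EEG low band (Hz), default 0.5-9.
#' @slot filterOrder Butterworth filter order.
#' @slot smoothWindow moving-average window in epochs.
#' @slot smoothFirst logical; if `TRUE` (default) smooth then log-transform,
#'   otherwise log-transform then smooth.
#' @export
setClass("FeatureConfig",
  representation(epochS = "numeric", emgBand = "numeric", deltaBand = "numeric",
                 thetaBand = "numeric", hiBand = "numeric", loBand = "numeric",
                 filterOrder = "integer", smoothWindow = "integer",
                 smoothFirst = "logical"),
  prototype(epochS = 4, emgBand = c(80, 100), deltaBand = c(0.5, 4),
            thetaBand = c(6, 9), hiBand = c(9, 45), loBand = c(0.5, 9),
            filterOrder = 3L, smoothWindow = 4L, smoothFirst = TRUE)
)

setValidity("FeatureConfig", function(object) {
  bands <- list(object@emgBand, object@deltaBand, object@thetaBand,
                object@hiBand, object@loBand)
  for (b in bands) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      return("each band must be a finite pair with 0 < low < high")
  }
  if (object@epochS <= 0) return("epochS must be positive")
  if (object@filterOrder < 1L) return("filterOrder must be >= 1")
  if (object@smoothWindow < 1L) return("smoothWindow must be >= 1")
  TRUE
})

#' Construct a FeatureConfig
#'
#' @param epochS epoch length (s).
#' @param emgBand,deltaBand,thetaBand,hiBand,loBand frequency bands (Hz pairs).
#' @param filterOrder Butterworth order.
#' @param smoothWindow moving-average window (epochs).
#' @param smoothFirst smooth before log-transforming (default) or after.
#' @return A [FeatureConfig-class] object.
#' @export
featureConfig <- function(epochS = 4, emgBand = c(80, 100),
                          deltaBand = c(0.5, 4), thetaBand = c(6, 9),
                          hiBand = c(9, 45), loBand = c(0.5, 9),
                          filterOrder = 3, smoothWindow = 4,
                          smoothFirst = TRUE) {
  new("FeatureConfig", epochS = epochS, emgBand = as.numeric(emgBand),
      deltaBand = as.numeric(deltaBand), thetaBand = as.numeric(thetaBand),
      hiBand = as.numeric(hiBand), loBand = as.numeric(loBand),
      filterOrder = as.integer(filterOrder),
      smoothWindow = as.integer(smoothWindow), smoothFirst = smoothFirst)
}

#' FeatureSeries: per-epoch EEG/EMG feature triplet
#'
#' Holds the three per-epoch features used for vigilance-state segmentation:
#' EMG r.m.s. power (muscle tone, 80-100 Hz band), the EEG delta/theta
#' mean-squared power ratio, and the EEG high/low (9-45 over 0.5-9 Hz) power
#' ratio. The `stage` flag records whether values are raw band powers
#' (strictly positive) or have been smoothed and log-transformed.
#'
#' @slot emgRMS numeric per-epoch EMG r.m.s. values.
#' @slot dtRatio numeric per-epoch delta/theta power ratios.
#' @slot hlRatio numeric per-epoch high/low power ratios.
#' @slot epochS epoch duration in seconds.
#' @slot stage `"raw"` or `"smoothed_log"`.
#' @export
setClass("FeatureSeries",
  representation(emgRMS = "numeric", dtRatio = "numeric", hlRatio = "numeric",
                 epochS = "numeric", stage = "character")
)

setValidity("FeatureSeries", function(object) {
  n <- length(object@emgRMS)
  if (length(object@dtRatio) != n || length(object@hlRatio) != n)
    return("feature series must have equal length")
  if (object@epochS <= 0) return("epochS must be positive")
  if (!object@stage %in% c("raw", "smoothed_log"))
    return("stage must be 'raw' or 'smoothed_log'")
  if (object@stage == "raw" &&
      n > 0 &&
      (any(object@emgRMS <= 0) || any(object@dtRatio <= 0) ||
       any(object@hlRatio <= 0)))
    return("raw-stage feature values must be strictly positive")
  if (object@stage == "smoothed_log" && n > 0 &&
      !(all(is.finite(object@emgRMS)) && all(is.finite(object@dtRatio)) &&
        all(is.finite(object@hlRatio))))
    return("smoothed_log feature values must be finite")
  TRUE
})

#' Construct a FeatureSeries
#'
#' @param emgRMS,dtRatio,hlRatio numeric vectors of equal length.
#' @param epochS epoch duration (s).
#' @param stage `"raw"` or `"smoothed_log"`.
#' @return A [FeatureSeries-class] object.
#' @export
featureSeries <- function(emgRMS, dtRatio, hlRatio, epochS = 4,
                          stage = c("raw", "smoothed_log")) {
  stage <- match.arg(stage)
  new("FeatureSeries", emgRMS = as.numeric(emgRMS),
      dtRatio = as.numeric(dtRatio), hlRatio = as.numeric(hlRatio),
      epochS = as.numeric(epochS), stage = stage)
}

#' Hypnogram: per-epoch vigilance labels
#'
#' A time-ordered sequence of WAKE/NREM/REM labels, one per scoring epoch.
#'
#' @slot labels character vector over `c("WAKE", "NREM", "REM")`.
#' @slot epochS epoch duration in seconds.
#' @export
setClass("Hypnogram",
  representation(labels = "character", epochS = "numeric")
)

setValidity("Hypnogram", function(object) {
  if (length(object@labels) == 0L) return("hypnogram must be non-empty")
  if (!all(object@labels %in% .STATES))
    return("labels must be WAKE, NREM or REM")
  if (length(object@epochS) != 1L || object@epochS <= 0)
    return("epochS must be a single positive number")
  TRUE
})

#' Construct a Hypnogram
#'
#' @param labels character or factor of per-epoch states
#'   (`"WAKE"`, `"NREM"`, `"REM"`).
#' @param epochS epoch duration (s).
#' @return A [Hypnogram-class] object.
#' @examples
#' hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "REM"))
#' @export
hypnogram <- function(labels, epochS = 4) {
  new("Hypnogram", labels = as.character(labels), epochS = as.numeric(epochS))
}

#' StateClusterModel: two-stage k-means vigilance-state clustering
#'
#' Result of the unsupervised two-stage clustering: stage 1 splits epochs into
#' Wake and sleep by 1-D k-means on EMG r.m.s. (higher centroid = WAKE);
#' stage 2 splits sleep into NREM and REM by 1-D k-means on the delta/theta
#' ratio (higher centroid = NREM). The per-state centroids in standardized
#' 3-D feature space support nearest-centroid scoring of new data.
#'
#' @slot emgCentroids two centroids on the smoothed-log EMG axis (sorted
#'   ascending; the larger maps to WAKE).
#' @slot sleepDtCentroids two centroids on the smoothed-log delta/theta axis
#'   fitted within the sleep cluster (the larger maps to NREM).
#' @slot stateCentroids 3 x 3 matrix of per-state centroids in standardized
#'   feature space; rows named WAKE, NREM, REM.
#' @slot featureMean,featureSd per-feature standardization constants
#'   (length 3, named).
#' @slot stateOrder fixed label ordering.
#' @slot trainLabels vigilance labels of the training epochs (two-stage
#'   cluster memberships).
#' @export
setClass("StateClusterModel",
  representation(emgCentroids = "numeric", sleepDtCentroids = "numeric",
                 stateCentroids = "matrix", featureMean = "numeric",
                 featureSd = "numeric", stateOrder = "character",
                 trainLabels = "character")
)

setValidity("StateClusterModel", function(object) {
  if (length(object@emgCentroids) != 2L ||
      length(object@sleepDtCentroids) != 2L)
    return("each 1-D stage must have exactly 2 centroids")
  if (!identical(dim(object@stateCentroids), c(3L, 3L)))
    return("stateCentroids must be 3 x 3")
  if (length(object@featureMean) != 3L || length(object@featureSd) != 3L)
    return("standardization constants must have length 3")
  if (any(object@featureSd <= 0)) return("featureSd must be strictly positive")
  if (!identical(object@stateOrder, .STATES))
    return("stateOrder must be WAKE, NREM, REM")
  TRUE
})

#' ObservationCodebook: vector-quantization centroids for HMM observations
#'
#' A set of M centroids (3 <= M <= 15) in standardized feature space chosen
#' as the smallest M whose k-means partition reaches a variance criterion
#' (between-cluster over total sum of squares) above a threshold, 0.90 by
#' default. Continuous feature vectors are mapped to the nearest centroid,
#' giving the discrete observation symbols of the HMM.
#'
#' @slot centroids M x 3 matrix of centroids in standardized feature space.
#' @slot M number of codebook symbols.
#' @slot vc achieved variance-criterion value in `[0, 1]`.
#' @slot vcThreshold target variance criterion.
#' @slot thresholdMet logical; `FALSE` when no M in range reached the
#'   threshold and the largest M was returned.
#' @slot featureMean,featureSd standardization constants shared with the
#'   clustering model.
#' @export
setClass("ObservationCodebook",
  representation(centroids = "matrix", M = "integer", vc = "numeric",
                 vcThreshold = "numeric", thresholdMet = "logical",
                 featureMean = "numeric", featureSd = "numeric")
)

setValidity("ObservationCodebook", function(object) {
  if (object@M < 3L || object@M > 15L) return("M must be in [3, 15]")
  if (nrow(object@centroids) != object@M || ncol(object@centroids) != 3L)
    return("centroids must be M x 3")
  if (anyDuplicated(object@centroids) > 0L)
    return("centroids must be pairwise distinct")
  if (object@vc < 0 || object@vc > 1) return("vc must be in [0, 1]")
  if (any(object@featureSd <= 0)) return("featureSd must be strictly positive")
  TRUE
})

setClassUnion("ObservationCodebookOrNULL", c("ObservationCodebook", "NULL"))

#' DiscretizedHMM: three-state HMM over codebook symbols
#'
#' A hidden Markov model whose latent states are the vigilance states and
#' whose observations are discrete codebook symbols: initial distribution
#' `pi`, 3 x 3 transition matrix `A`, and 3 x M emission matrix `B` giving
#' the conditional distribution of symbols in each state.
#'
#' @slot pi initial state distribution (length 3).
#' @slot A 3 x 3 row-stochastic transition matrix.
#' @slot B 3 x M row-stochastic emission matrix.
#' @slot codebook the [ObservationCodebook-class] the symbols refer to, or
#'   `NULL` for a free-standing model.
#' @slot stateOrder fixed label ordering.
#' @export
setClass("DiscretizedHMM",
  representation(pi = "numeric", A = "matrix", B = "matrix",
                 codebook = "ObservationCodebookOrNULL",
                 stateOrder = "character")
)

setValidity("DiscretizedHMM", function(object) {
  tol <- 1e-8
  if (length(object@pi) != 3L) return("pi must have length 3")
  if (!identical(dim(object@A), c(3L, 3L))) return("A must be 3 x 3")
  if (nrow(object@B) != 3L) return("B must have 3 rows")
  if (ncol(object@B) < 1L) return("B must have at least one column")
  if (any(object@pi < 0) || any(object@A < 0) || any(object@B < 0))
    return("probabilities must be non-negative")
  if (abs(sum(object@pi) - 1) > tol) return("pi must sum to 1")
  if (any(abs(rowSums(object@A) - 1) > tol))
    return("rows of A must sum to 1")
  if (any(abs(rowSums(object@B) - 1) > tol))
    return("rows of B must sum to 1")
  if (!is.null(object@codebook) && ncol(object@B) != object@codebook@M)
    return("B column count must equal codebook M")
  if (!identical(object@stateOrder, .STATES))
    return("stateOrder must be WAKE, NREM, REM")
  TRUE
})

#' Construct a DiscretizedHMM
#'
#' @param pi initial state distribution (length 3).
#' @param A 3 x 3 row-stochastic transition matrix.
#' @param B 3 x M row-stochastic emission matrix.
#' @param codebook optional [ObservationCodebook-class].
#' @return A [DiscretizedHMM-class] object.
#' @examples
#' A <- matrix(c(.9, .1, 0, .05, .9, .05, .1, .1, .8), 3, 3, byrow = TRUE)
#' B <- diag(3)
#' hmmModel(c(1, 0, 0), A, B)
#' @export
hmmModel <- function(pi, A, B, codebook = NULL) {
  B <- as.matrix(B)
  colnames(B) <- NULL
  A <- as.matrix(A)
  dimnames(A) <- list(.STATES, .STATES)
  new("DiscretizedHMM", pi = as.numeric(pi), A = A, B = B,
      codebook = codebook, stateOrder = .STATES)
}

#' StateFeatureModel: per-state Gaussian feature generator
#'
#' Parameterizes the per-state distribution of smoothed-log features as a
#' Gaussian with diagonal covariance, used by the synthetic-data module to
#' emulate the cluster geometry of real recordings: WAKE has high EMG tone;
#' NREM has low EMG and a high delta/theta ratio; REM has low EMG, a low
#' delta/theta ratio and a raised high/low ratio.
#'
#' @slot means 3 x 3 matrix of state means (rows WAKE/NREM/REM, columns
#'   emgRMS/dtRatio/hlRatio on the smoothed-log scale).
#' @slot sds 3 x 3 matrix of per-state, per-feature standard deviations.
#' @export
setClass("StateFeatureModel",
  representation(means = "matrix", sds = "matrix")
)

setValidity("StateFeatureModel", function(object) {
  if (!identical(dim(object@means), c(3L, 3L)) ||
      !identical(dim(object@sds), c(3L, 3L)))
    return("means and sds must be 3 x 3")
  if (any(object@sds <= 0)) return("all variances must be strictly positive")
  TRUE
})

#' VigilanceChain: Markov chain over vigilance states
#'
#' Transition matrix and initial distribution of the 3-state Markov chain
#' used to simulate ground-truth hypnograms.
#'
#' @slot A 3 x 3 row-stochastic transition matrix.
#' @slot pi initial distribution (length 3).
#' @export
setClass("VigilanceChain",
  representation(A = "matrix", pi = "numeric")
)

setValidity("VigilanceChain", function(object) {
  tol <- 1e-8
  if (!identical(dim(object@A), c(3L, 3L))) return("A must be 3 x 3")
  if (any(object@A < 0) || any(abs(rowSums(object@A) - 1) > tol))
    return("A rows must be stochastic")
  if (length(object@pi) != 3L || any(object@pi < 0) ||
      abs(sum(object@pi) - 1) > tol)
    return("pi must be a distribution over 3 states")
  TRUE
})

#' Construct a VigilanceChain
#'
#' @param A 3 x 3 row-stochastic transition matrix.
#' @param pi initial distribution; defaults to the stationary distribution
#'   of `A`.
#' @return A [VigilanceChain-class] object.
#' @export
vigilanceChain <- function(A, pi = NULL) {
  A <- as.matrix(A)
  dimnames(A) <- list(.STATES, .STATES)
  if (is.null(pi)) pi <- stationaryDistribution(A)
  new("VigilanceChain", A = A, pi = as.numeric(pi))
}

#' SleepStagingModel: complete fitted segmentation model
#'
#' Bundles the two-stage clustering model, the observation codebook and the
#' discretized-observation HMM fitted to one baseline recording, ready to
#' score new feature series by nearest centroid or by Viterbi decoding.
#'
#' @slot clusters fitted [StateClusterModel-class].
#' @slot codebook fitted [ObservationCodebook-class].
#' @slot hmm fitted [DiscretizedHMM-class].
#' @slot baumWelch logical; whether Baum-Welch refinement was applied.
#' @slot logLikTrace per-iteration log-likelihood trace of Baum-Welch
#'   (length 0 when refinement was off).
#' @export
setClass("SleepStagingModel",
  representation(clusters = "StateClusterModel",
                 codebook = "ObservationCodebook",
                 hmm = "DiscretizedHMM",
                 baumWelch = "logical",
                 logLikTrace = "numeric")
)
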