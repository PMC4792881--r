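#' Number of scoring epochs
#'
#' @param x a [FeatureSeries-class] or [Hypnogram-class].
#' @return integer epoch count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "FeatureSeries", function(x) length(x@emgRMS))

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@labels))

#' Epoch duration in seconds
#'
#' @param x a [FeatureSeries-class] or [Hypnogram-class].
#' @return numeric scalar, seconds per epoch.
#' @export
setGeneric("epochDuration", function(x) standardGeneric("epochDuration"))

#' @rdname epochDuration
#' @export
setMethod("epochDuration", "FeatureSeries", function(x) x@epochS)

#' @rdname epochDuration
#' @export
setMethod("epochDuration", "Hypnogram", function(x) x@epochS)

#' Per-epoch state labels of a hypnogram
#'
#' @param x a [Hypnogram-class].
#' @return character vector of `"WAKE"`/`"NREM"`/`"REM"` labels.
#' @export
stateLabels <- function(x) {
  stopifnot(is(x, "Hypnogram"))
  x@labels
}

#' Feature matrix of a FeatureSeries
#'
#' @param x a [FeatureSeries-class].
#' @return numeric matrix with one row per epoch and columns
#'   `emg_rms`, `dt_ratio`, `hl_ratio`.
#' @export
featureMatrix <- function(x) {
  stopifnot(is(x, "FeatureSeries"))
  cbind(emg_rms = x@emgRMS, dt_ratio = x@dtRatio, hl_ratio = x@hlRatio)
}

#' Processing stage of a FeatureSeries
#'
#' @param x a [FeatureSeries-class].
#' @return `"raw"` or `"smoothed_log"`.
#' @export
featureStage <- function(x) {
  stopifnot(is(x, "FeatureSeries"))
  x@stage
}

#' Transition matrix of a model
#'
#' @param x a [DiscretizedHMM-class] or [VigilanceChain-class].
#' @return 3 x 3 row-stochastic matrix.
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "DiscretizedHMM", function(x) x@A)

#' @rdname transitionMatrix
#' @export
setMethod("transitionMatrix", "VigilanceChain", function(x) x@A)

#' Emission matrix of a DiscretizedHMM
#'
#' @param x a [DiscretizedHMM-class].
#' @return 3 x M row-stochastic matrix of symbol probabilities per state.
#' @export
emissionMatrix <- function(x) {
  stopifnot(is(x, "DiscretizedHMM"))
  x@B
}

#' Initial state distribution
#'
#' @param x a [DiscretizedHMM-class] or [VigilanceChain-class].
#' @return numeric length-3 probability vector.
#' @export
setGeneric("initialDistribution",
           function(x) standardGeneric("initialDistribution"))

#' @rdname initialDistribution
#' @export
setMethod("initialDistribution", "DiscretizedHMM", function(x) x@pi)

#' @rdname initialDistribution
#' @export
setMethod("initialDistribution", "VigilanceChain", function(x) x@pi)

#' Codebook size
#'
#' @param x an [ObservationCodebook-class] or [DiscretizedHMM-class].
#' @return integer number of codebook symbols M.
#' @export
setGeneric("codebookSize", function(x) standardGeneric("codebookSize"))

#' @rdname codebookSize
#' @export
setMethod("codebookSize", "ObservationCodebook", function(x) x@M)

#' @rdname codebookSize
#' @export
setMethod("codebookSize", "DiscretizedHMM", function(x) ncol(x@B))

setMethod("show", "SignalRecording", function(object) {
  n <- length(object@eeg)
  cat(sprintf("SignalRecording: %d samples x 2 channels (EEG, EMG), %g Hz (%.1f s)\n",
              n, object@fs, n / object@fs))
})

setMethod("show", "FeatureSeries", function(object) {
  cat(sprintf("FeatureSeries: %d epochs of %g s, stage '%s'\n",
              nEpochs(object), object@epochS, object@stage))
  if (nEpochs(object) > 0) {
    m <- featureMatrix(object)
    rng <- apply(m, 2, range)
    cat(sprintf("  emg_rms [%.3g, %.3g]  dt_ratio [%.3g, %.3g]  hl_ratio [%.3g, %.3g]\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  }
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@labels, levels = .STATES))
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h)\n", length(object@labels),
              object@epochS, length(object@labels) * object@epochS / 3600))
  pct <- 100 * tab / sum(tab)
  cat(sprintf("  WAKE %.1f%%  NREM %.1f%%  REM %.1f%%\n",
              pct["WAKE"], pct["NREM"], pct["REM"]))
})

setMethod("show", "StateClusterModel", function(object) {
  cat("StateClusterModel (two-stage k-means)\n")
  cat(sprintf("  EMG centroids (sleep | wake): %.3f | %.3f\n",
              min(object@emgCentroids), max(object@emgCentroids)))
  cat(sprintf("  sleep delta/theta centroids (REM | NREM): %.3f | %.3f\n",
              min(object@sleepDtCentroids), max(object@sleepDtCentroids)))
  tab <- table(factor(object@trainLabels, levels = .STATES))
  cat(sprintf("  training epochs: %d (WAKE %d, NREM %d, REM %d)\n",
              length(object@trainLabels), tab["WAKE"], tab["NREM"], tab["REM"]))
})

setMethod("show", "ObservationCodebook", function(object) {
  cat(sprintf("ObservationCodebook: M = %d symbols, VC = %.3f (threshold %.2f%s)\n",
              object@M, object@vc, object@vcThreshold,
              if (object@thresholdMet) "" else ", not reached"))
})

setMethod("show", "DiscretizedHMM", function(object) {
  cat(sprintf("DiscretizedHMM: 3 states x %d symbols\n", ncol(object@B)))
  cat("  transition matrix:\n")
  print(round(object@A, 4))
  cat("  pi:", paste(sprintf("%.4f", object@pi), collapse = " "), "\n")
})

setMethod("show", "VigilanceChain", function(object) {
  cat("VigilanceChain (3-state Markov chain)\n")
  print(round(object@A, 4))
  cat("  pi:", paste(sprintf("%.4f", object@pi), collapse = " "), "\n")
})

setMethod("show", "StateFeatureModel", function(object) {
  cat("StateFeatureModel (Gaussian, diagonal covariance)\n")
  cat("  means:\n"); print(round(object@means, 3))
})

setMethod("show", "SleepStagingModel", function(object) {
  cat("SleepStagingModel\n")
  cat(sprintf("  codebook: M = %d (VC %.3f)\n", object@codebook@M,
              object@codebook@vc))
  cat(sprintf("  Baum-Welch: %s%s\n",
              if (object@baumWelch) "on" else "off (initial-guess HMM)",
              if (object@baumWelch)
                sprintf(", %d iterations, final logLik %.2f",
                        length(object@logLikTrace),
                        utils::tail(object@logLikTrace, 1)) else ""))
})
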