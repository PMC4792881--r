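#' Fit the full unsupervised staging model to a baseline recording
#'
#' Runs the complete unsupervised fitting sequence on a smoothed-log
#' feature series: (1) two-stage k-means clustering into Wake/NREM/REM;
#' (2) codebook selection by the variance criterion; (3) HMM initialization
#' from the cluster memberships and quantized symbols; (4) optional
#' Baum-Welch refinement (on by default).
#'
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @param seed RNG seed used for all k-means stages (default 0).
#' @param restarts k-means restarts (default 10).
#' @param kmin,kmax,vcThreshold codebook-selection parameters
#'   (see [fitCodebook()]).
#' @param baumWelch apply Baum-Welch refinement (default `TRUE`); with
#'   `FALSE` the initial-guess HMM is kept.
#' @param tol,maxIter,floorProb HMM estimation parameters
#'   (see [baumWelch()] and [initHMM()]).
#' @param piMode initial-distribution mode (see [initHMM()]).
#' @return A [SleepStagingModel-class].
#' @examples
#' h <- simulateHypnogram(lightChain(), T = 600, seed = 1)
#' f <- simulateFeatures(h, seed = 2)
#' fit <- fitSleepModel(f, seed = 0)
#' fit
#' @export
fitSleepModel <- function(feats, seed = 0, restarts = 10, kmin = 3,
                          kmax = 15, vcThreshold = 0.90, baumWelch = TRUE,
                          tol = 1e-6, maxIter = 500, floorProb = 1e-6,
                          piMode = "stationary") {
  clusters <- fitStateClusters(feats, seed = seed, restarts = restarts)
  codebook <- fitCodebook(feats, kmin = kmin, kmax = kmax,
                          vcThreshold = vcThreshold, seed = seed,
                          restarts = restarts)
  symbols <- quantizeFeatures(codebook, feats)
  states <- hypnogram(clusters@trainLabels, epochS = feats@epochS)
  hmm <- initHMM(symbols, states, codebook, floorProb = floorProb,
                 piMode = piMode)
  trace <- numeric(0)
  if (baumWelch) {
    bw <- baumWelch(hmm, symbols, tol = tol, maxIter = maxIter,
                    floorProb = floorProb)
    hmm <- bw$model
    trace <- bw$logLik
  }
  new("SleepStagingModel", clusters = clusters, codebook = codebook,
      hmm = hmm, baumWelch = baumWelch, logLikTrace = trace)
}

#' Score a feature series with a fitted model
#'
#' Produces a hypnogram from smoothed-log features using either Viterbi
#' decoding of the discretized-observation HMM (`method = "hmm"`, the
#' default) or per-epoch nearest-centroid assignment to the three state
#' centroids (`method = "kmeans"`, which ignores state dynamics).
#'
#' @param model a [SleepStagingModel-class].
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @param method `"hmm"` or `"kmeans"`.
#' @return A [Hypnogram-class] aligned to `feats`.
#' @export
scoreSleep <- function(model, feats, method = c("hmm", "kmeans")) {
  stopifnot(is(model, "SleepStagingModel"), is(feats, "FeatureSeries"))
  method <- match.arg(method)
  if (method == "kmeans") {
    assignStates(model@clusters, feats)
  } else {
    symbols <- quantizeFeatures(model@codebook, feats)
    viterbiDecode(model@hmm, symbols, epochS = feats@epochS)$hypnogram
  }
}
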