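#' Zero-phase Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass filter forward and backward
#' (zero-phase, via [signal::filtfilt()]), so the effective magnitude
#' response is the squared single-pass response and no phase lag is
#' introduced at epoch boundaries.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param lo,hi passband edges (Hz); must satisfy `0 < lo < hi < fs/2`.
#' @param order filter order (default 3).
#' @return filtered numeric vector of the same length as `x`.
#' @examples
#' t <- seq(0, 10, by = 1/400)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 50 * t)
#' y <- bandpass(x, fs = 400, lo = 0.5, hi = 4)   # keeps the 2 Hz component
#' @export
bandpass <- function(x, fs, lo, hi, order = 3) {
  if (!(is.finite(lo) && is.finite(hi) && lo > 0 && lo < hi && hi < fs / 2))
    stop("invalid band: need 0 < lo < hi < fs/2 (Nyquist)")
  # filtfilt needs enough samples for its edge treatment of a filter whose
  # coefficient vectors have 2*order + 1 taps
  if (length(x) <= 3 * (2 * order + 1))
    stop("signal too short for stable order-", order, " bandpass filtering")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Per-epoch mean of squared samples; trailing partial epoch discarded.
epochMeanSquare <- function(x, samplesPerEpoch) {
  n <- floor(length(x) / samplesPerEpoch)
  m <- matrix(x[seq_len(n * samplesPerEpoch)]^2, nrow = samplesPerEpoch)
  colMeans(m)
}

#' Extract per-epoch EEG/EMG features
#'
#' Computes the three raw features used for vigilance-state segmentation in
#' every epoch of a recording: the r.m.s. of the 80-100 Hz-filtered EMG
#' (muscle tone), the ratio of mean-squared EEG power in the delta
#' (0.5-4 Hz) over the theta (6-9 Hz) band, and the ratio of mean-squared
#' EEG power in a high (9-45 Hz) over a low (0.5-9 Hz) band. Each band is
#' isolated with a zero-phase 3rd-order Butterworth filter applied once to
#' the whole channel before epoching, avoiding per-epoch filter transients.
#' A trailing partial epoch is discarded.
#'
#' Denominator powers are floored at `1e-12` (squared microvolts) so silent
#' channels never produce infinite ratios.
#'
#' @param rec a [SignalRecording-class].
#' @param cfg a [FeatureConfig-class]; defaults to standard bands, 4-s
#'   epochs, order-3 filters.
#' @return A [FeatureSeries-class] with `stage = "raw"` and
#'   `floor(length / (fs * epochS))` epochs.
#' @seealso [smoothAndLog()] for the preprocessing applied before clustering.
#' @export
extractFeatures <- function(rec, cfg = featureConfig()) {
  stopifnot(is(rec, "SignalRecording"), is(cfg, "FeatureConfig"))
  spe <- cfg@epochS * rec@fs
  if (abs(spe - round(spe)) > 1e-9)
    stop("epochS * fs must be a whole number of samples")
  spe <- as.integer(round(spe))
  if (length(rec@eeg) < spe)
    stop("recording shorter than one epoch")
  ord <- cfg@filterOrder

  emgF   <- bandpass(rec@emg, rec@fs, cfg@emgBand[1], cfg@emgBand[2], ord)
  delta  <- bandpass(rec@eeg, rec@fs, cfg@deltaBand[1], cfg@deltaBand[2], ord)
  theta  <- bandpass(rec@eeg, rec@fs, cfg@thetaBand[1], cfg@thetaBand[2], ord)
  hiBand <- bandpass(rec@eeg, rec@fs, cfg@hiBand[1], cfg@hiBand[2], ord)
  loBand <- bandpass(rec@eeg, rec@fs, cfg@loBand[1], cfg@loBand[2], ord)

  emgMS <- pmax(epochMeanSquare(emgF, spe), .POWER_FLOOR)
  dNum  <- pmax(epochMeanSquare(delta, spe), .POWER_FLOOR)
  tDen  <- pmax(epochMeanSquare(theta, spe), .POWER_FLOOR)
  hNum  <- pmax(epochMeanSquare(hiBand, spe), .POWER_FLOOR)
  lDen  <- pmax(epochMeanSquare(loBand, spe), .POWER_FLOOR)

  featureSeries(emgRMS = sqrt(emgMS), dtRatio = dNum / tDen,
                hlRatio = hNum / lDen, epochS = cfg@epochS, stage = "raw")
}

# Trailing (causal) moving average: mean over the current epoch and the
# window-1 preceding ones, with shrinking windows at the start.
trailingMean <- function(x, window) {
  if (window <= 1L) return(x)
  cs <- cumsum(x)
  n <- length(x)
  out <- numeric(n)
  idx <- seq_len(n)
  lo <- pmax(idx - window, 0L)
  out <- (cs[idx] - c(0, cs)[lo + 1L]) / (idx - lo)
  out
}

#' Smooth and log-transform a raw feature series
#'
#' Applies a trailing moving average over `window` epochs (the current epoch
#' plus the preceding `window - 1`; shorter windows at the start of the
#' recording), then a natural-log transform, to each of the three feature
#' series. Smoothing reduces epoch-to-epoch noise; the log reduces the
#' skewness typical of signal-power estimates. Values are floored at
#' `1e-12` before the log so the output is always finite.
#'
#' @param x a [FeatureSeries-class] with `stage = "raw"`.
#' @param window moving-average length in epochs (default 4, i.e. 16 s at
#'   4-s epochs).
#' @param smoothFirst if `TRUE` (default) smooth then log-transform;
#'   otherwise log-transform then smooth.
#' @return A [FeatureSeries-class] with `stage = "smoothed_log"` and the
#'   same number of epochs.
#' @export
smoothAndLog <- function(x, window = 4, smoothFirst = TRUE) {
  stopifnot(is(x, "FeatureSeries"))
  if (x@stage != "raw")
    stop("smoothAndLog expects a raw-stage FeatureSeries")
  window <- as.integer(window)
  stopifnot(window >= 1L)
  tf <- if (smoothFirst) {
    function(v) log(pmax(trailingMean(v, window), .POWER_FLOOR))
  } else {
    function(v) trailingMean(log(pmax(v, .POWER_FLOOR)), window)
  }
  featureSeries(emgRMS = tf(x@emgRMS), dtRatio = tf(x@dtRatio),
                hlRatio = tf(x@hlRatio), epochS = x@epochS,
                stage = "smoothed_log")
}
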