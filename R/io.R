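# CSV interchange, model JSON serialization, and a minimal EDF codec.
# All CSVs are UTF-8, '.'-decimal, with a mandatory header; lines beginning
# with '#' carry provenance and are skipped on read.

provenanceLines <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("sleepHMM"))
  c(sprintf("# sleepHMM %s", ver),
    if (!is.null(seed)) sprintf("# seed %d", as.integer(seed)))
}

writeCSVWithHeader <- function(df, path, seed = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(provenanceLines(seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a feature series to CSV
#'
#' Columns: `epoch_index` (0-based), `start_s` (`epoch_index * epochS`),
#' `emg_rms`, `dt_ratio`, `hl_ratio`, `stage`.
#'
#' @param feats a [FeatureSeries-class].
#' @param path output file path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(feats, path, seed = NULL) {
  stopifnot(is(feats, "FeatureSeries"))
  idx <- seq_len(nEpochs(feats)) - 1L
  df <- data.frame(epoch_index = idx, start_s = idx * feats@epochS,
                   emg_rms = feats@emgRMS, dt_ratio = feats@dtRatio,
                   hl_ratio = feats@hlRatio, stage = feats@stage)
  writeCSVWithHeader(df, path, seed)
}

#' Read a feature series from CSV
#'
#' @param path file written by [writeFeatureCSV()] (or any CSV with columns
#'   `emg_rms`, `dt_ratio`, `hl_ratio` and, optionally, `start_s` and
#'   `stage`).
#' @param epochS epoch duration used when the file has no `start_s` column.
#' @return A [FeatureSeries-class].
#' @export
readFeatureCSV <- function(path, epochS = 4) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("emg_rms", "dt_ratio", "hl_ratio")
  if (!all(need %in% names(df)))
    stop("feature CSV must contain columns ", paste(need, collapse = ", "))
  if ("start_s" %in% names(df) && nrow(df) > 1L)
    epochS <- df$start_s[2] - df$start_s[1]
  stage <- if ("stage" %in% names(df)) as.character(df$stage[1]) else "smoothed_log"
  featureSeries(df$emg_rms, df$dt_ratio, df$hl_ratio, epochS = epochS,
                stage = stage)
}

#' Write a hypnogram to CSV
#'
#' Columns: `epoch_index` (0-based), `start_s`, `label`
#' (WAKE/NREM/REM).
#'
#' @param h a [Hypnogram-class].
#' @param path output file path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
writeHypnogramCSV <- function(h, path, seed = NULL) {
  stopifnot(is(h, "Hypnogram"))
  idx <- seq_len(nEpochs(h)) - 1L
  df <- data.frame(epoch_index = idx, start_s = idx * h@epochS,
                   label = h@labels)
  writeCSVWithHeader(df, path, seed)
}

#' Read a hypnogram from CSV
#'
#' @param path file with columns `label` and, optionally, `start_s`.
#' @param epochS epoch duration used when the file has no `start_s` column.
#' @return A [Hypnogram-class].
#' @export
readHypnogramCSV <- function(path, epochS = 4) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!"label" %in% names(df)) stop("hypnogram CSV must contain 'label'")
  if ("start_s" %in% names(df) && nrow(df) > 1L)
    epochS <- df$start_s[2] - df$start_s[1]
  hypnogram(df$label, epochS = epochS)
}

#' Read a two-channel signal CSV
#'
#' @param path CSV with columns `eeg` and `emg` (samples in microvolts).
#' @param fs sampling rate in Hz (not stored in the CSV).
#' @return A [SignalRecording-class].
#' @export
readSignalCSV <- function(path, fs) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("eeg", "emg") %in% names(df)))
    stop("signal CSV must contain columns 'eeg' and 'emg'")
  signalRecording(df$eeg, df$emg, fs = fs)
}

#' Write a two-channel signal CSV
#'
#' @param rec a [SignalRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSignalCSV <- function(rec, path) {
  stopifnot(is(rec, "SignalRecording"))
  utils::write.csv(data.frame(eeg = rec@eeg, emg = rec@emg), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

.codebookToList <- function(cb) {
  list(M = cb@M, centroids = cb@centroids, vc = cb@vc,
       vc_threshold = cb@vcThreshold, threshold_met = cb@thresholdMet,
       feature_mean = as.list(cb@featureMean),
       feature_sd = as.list(cb@featureSd))
}

.codebookFromList <- function(x) {
  new("ObservationCodebook",
      centroids = matrix(unlist(x$centroids), nrow = x$M),
      M = as.integer(x$M), vc = x$vc, vcThreshold = x$vc_threshold,
      thresholdMet = x$threshold_met,
      featureMean = unlist(x$feature_mean), featureSd = unlist(x$feature_sd))
}

#' Save a fitted staging model as JSON
#'
#' Serializes a [SleepStagingModel-class] (standardization constants, all
#' centroid sets, state order, codebook, HMM probabilities and training
#' metadata) with full numeric precision, so that save/load round-trips
#' preserve every probability bit-exactly.
#'
#' @param model a [SleepStagingModel-class].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
saveModelJSON <- function(model, path) {
  stopifnot(is(model, "SleepStagingModel"))
  cl <- model@clusters
  obj <- list(
    package = "sleepHMM",
    version = as.character(utils::packageVersion("sleepHMM")),
    state_order = cl@stateOrder,
    clusters = list(
      emg_centroids = cl@emgCentroids,
      sleep_dt_centroids = cl@sleepDtCentroids,
      state_centroids = cl@stateCentroids,
      feature_mean = as.list(cl@featureMean),
      feature_sd = as.list(cl@featureSd),
      train_labels = cl@trainLabels),
    codebook = .codebookToList(model@codebook),
    hmm = list(pi = model@hmm@pi, A = model@hmm@A, B = model@hmm@B),
    baum_welch = model@baumWelch,
    loglik_trace = model@logLikTrace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a fitted staging model from JSON
#'
#' @param path file written by [saveModelJSON()].
#' @return A [SleepStagingModel-class].
#' @export
loadModelJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$hmm)) stop("not a sleepHMM model file: ", path)
  cl <- new("StateClusterModel",
            emgCentroids = as.numeric(x$clusters$emg_centroids),
            sleepDtCentroids = as.numeric(x$clusters$sleep_dt_centroids),
            stateCentroids = matrix(as.numeric(x$clusters$state_centroids),
                                    3, 3,
                                    dimnames = list(x$state_order,
                                                    names(x$clusters$feature_mean))),
            featureMean = unlist(x$clusters$feature_mean),
            featureSd = unlist(x$clusters$feature_sd),
            stateOrder = as.character(x$state_order),
            trainLabels = as.character(x$clusters$train_labels))
  cb <- .codebookFromList(x$codebook)
  hmm <- hmmModel(as.numeric(x$hmm$pi),
                  matrix(as.numeric(unlist(x$hmm$A)), 3, 3),
                  matrix(as.numeric(unlist(x$hmm$B)), 3, cb@M),
                  codebook = cb)
  new("SleepStagingModel", clusters = cl, codebook = cb, hmm = hmm,
      baumWelch = isTRUE(x$baum_welch),
      logLikTrace = as.numeric(x$loglik_trace %||% numeric(0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Minimal EDF (European Data Format) support ----------------------------
# Continuous recordings, int16 little-endian samples, identical record
# structure for all signals. Covers standard EDF; EDF+ annotations are not
# supported.

padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a SignalRecording to an EDF file
#'
#' Writes a two-signal (EEG, EMG) standard EDF file with 1-s data records
#' and 16-bit samples scaled to each channel's physical range.
#'
#' @param rec a [SignalRecording-class]; `fs` must be a whole number and the
#'   recording is truncated to a whole number of seconds.
#' @param path output file path.
#' @param labels channel labels (default `c("EEG", "EMG")`).
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path, labels = c("EEG", "EMG")) {
  stopifnot(is(rec, "SignalRecording"))
  fs <- rec@fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires integer fs")
  fs <- as.integer(round(fs))
  nRec <- floor(length(rec@eeg) / fs)
  if (nRec < 1) stop("recording shorter than one 1-s EDF record")
  chans <- list(rec@eeg[seq_len(nRec * fs)], rec@emg[seq_len(nRec * fs)])
  ns <- 2L

  physMin <- vapply(chans, function(x) min(x, -1e-6), 0)
  physMax <- vapply(chans, function(x) max(x, 1e-6), 0)
  digMin <- -32768; digMax <- 32767

  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(paste0(
    padField("0", 8),
    padField("X X X X", 80),
    padField("synthetic recording", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(as.character(256L * (1L + ns)), 8),
    padField("", 44),
    padField(as.character(nRec), 8),
    padField("1", 8),
    padField(as.character(ns), 4)), con, eos = NULL)
  fld <- function(vals, width)
    writeChar(paste0(vapply(vals, padField, "", width = width),
                     collapse = ""), con, eos = NULL)
  fld(labels, 16)
  fld(rep("", ns), 80)                       # transducer
  fld(rep("uV", ns), 8)                      # physical dimension
  fld(formatC(physMin, format = "g", digits = 6), 8)
  fld(formatC(physMax, format = "g", digits = 6), 8)
  fld(rep(as.character(digMin), ns), 8)
  fld(rep(as.character(digMax), ns), 8)
  fld(rep("", ns), 80)                       # prefiltering
  fld(rep(as.character(fs), ns), 8)          # samples per record
  fld(rep("", ns), 32)                       # reserved

  # re-read written header physical ranges so digitization matches readers
  gain <- (digMax - digMin) /
    (as.numeric(formatC(physMax, format = "g", digits = 6)) -
     as.numeric(formatC(physMin, format = "g", digits = 6)))
  pm <- as.numeric(formatC(physMin, format = "g", digits = 6))
  for (r in seq_len(nRec)) {
    for (ch in 1:2) {
      seg <- chans[[ch]][((r - 1) * fs + 1):(r * fs)]
      dig <- round((seg - pm[ch]) * gain[ch] + digMin)
      dig <- pmin(pmax(dig, digMin), digMax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a two-channel EDF file
#'
#' Minimal reader for continuous standard EDF: parses the header, reads all
#' data records, converts digital values to physical units, and selects the
#' EEG and EMG channels by label.
#'
#' @param path EDF file path.
#' @param eegLabel,emgLabel channel labels to select (matched on the
#'   trimmed label's first word, case-insensitive prefix).
#' @return A [SignalRecording-class].
#' @export
readEDF <- function(path, eegLabel = "EEG", emgLabel = "EMG") {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  if (nchar(hdr) < 256) stop("corrupt EDF: truncated header")
  gethdr <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  nRec <- suppressWarnings(as.integer(gethdr(hdr, 237, 8)))
  recDur <- suppressWarnings(as.numeric(gethdr(hdr, 245, 8)))
  ns <- suppressWarnings(as.integer(gethdr(hdr, 253, 4)))
  if (is.na(ns) || ns < 1 || is.na(nRec) || nRec < 1 || is.na(recDur))
    stop("corrupt EDF: bad header fields")
  shdr <- rawToChar(readBin(con, "raw", 256 * ns))
  if (nchar(shdr) < 256 * ns) stop("corrupt EDF: truncated signal header")
  field <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns) - 1L, function(i)
      trimws(substr(shdr, start + i * width + 1, start + (i + 1) * width)),
      "")
  }
  labels <- field(0, 16)
  physMin <- as.numeric(field(16 + 80 + 8, 8))
  physMax <- as.numeric(field(16 + 80 + 8 + 8, 8))
  digMin <- as.numeric(field(16 + 80 + 8 + 16, 8))
  digMax <- as.numeric(field(16 + 80 + 8 + 24, 8))
  spr <- as.integer(field(16 + 80 + 8 + 32 + 80, 8))
  if (anyNA(c(physMin, physMax, digMin, digMax, spr)))
    stop("corrupt EDF: bad signal header fields")

  data <- vector("list", ns)
  for (i in seq_len(ns)) data[[i]] <- matrix(NA_real_, spr[i], nRec)
  for (r in seq_len(nRec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (length(v) < spr[i]) stop("corrupt EDF: truncated data records")
      data[[i]][, r] <- v
    }
  }
  phys <- lapply(seq_len(ns), function(i) {
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    physMin[i] + (as.numeric(data[[i]]) - digMin[i]) * gain
  })
  pick <- function(lab) {
    hit <- which(startsWith(toupper(labels), toupper(lab)))
    if (!length(hit)) stop("no channel with label starting '", lab, "'")
    hit[1]
  }
  iEEG <- pick(eegLabel); iEMG <- pick(emgLabel)
  fs <- spr[iEEG] / recDur
  if (spr[iEMG] != spr[iEEG])
    stop("EEG and EMG channels have different sampling rates")
  signalRecording(phys[[iEEG]], phys[[iEMG]], fs = fs)
}
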