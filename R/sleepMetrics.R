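#' Run-length bouts of a hypnogram
#'
#' A bout is a maximal run of consecutive epochs in the same vigilance
#' state. Bouts tile the hypnogram exactly; consecutive bouts always differ
#' in state. First and last runs count as full bouts.
#'
#' @param h a [Hypnogram-class].
#' @return data.frame with columns `state`, `start_epoch` (0-based),
#'   `length_epochs`.
#' @examples
#' bouts(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM", "REM", "WAKE")))
#' @export
bouts <- function(h) {
  stopifnot(is(h, "Hypnogram"))
  r <- rle(h@labels)
  data.frame(state = r$values,
             start_epoch = cumsum(c(0L, r$lengths[-length(r$lengths)])),
             length_epochs = r$lengths,
             stringsAsFactors = FALSE)
}

#' Sleep metrics of a hypnogram
#'
#' Per-state summary of sleep architecture: percent of recording time,
#' number of bouts, and mean bout duration in seconds. A state absent from
#' the hypnogram gets 0% time, 0 bouts and `NA` mean bout duration ("no
#' bouts" is distinct from "zero-length bouts").
#'
#' @param h a [Hypnogram-class].
#' @return data.frame with one row per state (WAKE, NREM, REM) and columns
#'   `state`, `percent_time`, `n_bouts`, `mean_bout_s`.
#' @examples
#' sleepMetrics(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM",
#'                          "REM", "WAKE")))
#' @export
sleepMetrics <- function(h) {
  stopifnot(is(h, "Hypnogram"))
  b <- bouts(h)
  total <- length(h@labels)
  out <- lapply(.STATES, function(s) {
    bl <- b$length_epochs[b$state == s]
    data.frame(state = s,
               percent_time = 100 * sum(bl) / total,
               n_bouts = length(bl),
               mean_bout_s = if (length(bl)) mean(bl) * h@epochS else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Agreement between a reference and a predicted hypnogram
#'
#' Epoch-by-epoch confusion matrix (reference in rows, prediction in
#' columns), overall percent agreement, and per-state one-vs-rest
#' sensitivity (`100 TP / (TP + FN)`) and specificity (`100 TN / (TN + FP)`).
#'
#' @param ref reference [Hypnogram-class] (e.g. manual scores).
#' @param pred predicted [Hypnogram-class] of equal length and epoch
#'   duration.
#' @return list with `confusion` (3 x 3 count matrix), `overall` (percent),
#'   and `perState` (data.frame with `state`, `sensitivity`, `specificity`).
#' @export
agreement <- function(ref, pred) {
  stopifnot(is(ref, "Hypnogram"), is(pred, "Hypnogram"))
  if (nEpochs(ref) != nEpochs(pred))
    stop("alignment error: hypnograms differ in length")
  if (abs(ref@epochS - pred@epochS) > 1e-9)
    stop("alignment error: hypnograms differ in epoch duration")
  conf <- table(factor(ref@labels, levels = .STATES),
                factor(pred@labels, levels = .STATES))
  conf <- matrix(as.numeric(conf), 3, 3, dimnames = list(.STATES, .STATES))
  total <- sum(conf)
  overall <- 100 * sum(diag(conf)) / total
  perState <- do.call(rbind, lapply(seq_along(.STATES), function(i) {
    tp <- conf[i, i]
    fn <- sum(conf[i, ]) - tp
    fp <- sum(conf[, i]) - tp
    tn <- total - tp - fn - fp
    data.frame(state = .STATES[i],
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(confusion = conf, overall = overall, perState = perState)
}

.metricNames <- c("percent_time", "n_bouts", "mean_bout_s")

#' Compare two automatic scorers against reference hypnograms
#'
#' Given per-subject reference hypnograms and the hypnograms produced by two
#' scorers (nearest-centroid k-means and the HMM), computes, for every
#' subject, state and metric, the signed error (predicted minus reference)
#' in percent time, bout number and mean bout duration. Across subjects it
#' runs, per scorer/state/metric, a Wilcoxon signed-rank test of the errors
#' against zero (exact distribution for small samples, mid-ranks for ties,
#' as in [stats::wilcox.test()]), and computes the Spearman rank correlation
#' between predicted and reference metric values.
#'
#' @param refs list of reference [Hypnogram-class] objects, one per subject.
#' @param predsKM list of k-means-scored hypnograms, aligned with `refs`.
#' @param predsHMM list of HMM-scored hypnograms, aligned with `refs`.
#' @return list with `errors` (data.frame: subject, scorer, state, metric,
#'   reference, predicted, error), `tests` (scorer, state, metric,
#'   wilcoxon_p), and `correlations` (scorer, state, metric, spearman_rho).
#' @export
compareScorers <- function(refs, predsKM, predsHMM) {
  n <- length(refs)
  if (n < 2L) stop("need at least 2 subjects for the paired tests")
  stopifnot(length(predsKM) == n, length(predsHMM) == n)

  rows <- list()
  for (s in seq_len(n)) {
    mref <- sleepMetrics(refs[[s]])
    for (scorer in c("kmeans", "hmm")) {
      mp <- sleepMetrics(if (scorer == "kmeans") predsKM[[s]] else predsHMM[[s]])
      for (metric in .metricNames) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, scorer = scorer, state = .STATES,
          metric = metric, reference = mref[[metric]],
          predicted = mp[[metric]],
          error = mp[[metric]] - mref[[metric]],
          stringsAsFactors = FALSE)
      }
    }
  }
  errors <- do.call(rbind, rows)

  combos <- expand.grid(scorer = c("kmeans", "hmm"), state = .STATES,
                        metric = .metricNames, stringsAsFactors = FALSE)
  tests <- combos
  tests$wilcoxon_p <- NA_real_
  cors <- combos
  cors$spearman_rho <- NA_real_
  for (i in seq_len(nrow(combos))) {
    sel <- errors$scorer == combos$scorer[i] &
      errors$state == combos$state[i] & errors$metric == combos$metric[i]
    e <- errors$error[sel]
    x <- errors$reference[sel]
    y <- errors$predicted[sel]
    ok <- is.finite(e)
    if (sum(ok) >= 2L && any(e[ok] != 0)) {
      tests$wilcoxon_p[i] <- suppressWarnings(
        stats::wilcox.test(e[ok], mu = 0)$p.value)
    } else if (sum(ok) >= 2L) {
      tests$wilcoxon_p[i] <- 1
    }
    okxy <- is.finite(x) & is.finite(y)
    if (sum(okxy) >= 2L && stats::sd(x[okxy]) > 0 && stats::sd(y[okxy]) > 0)
      cors$spearman_rho[i] <- stats::cor(x[okxy], y[okxy], method = "spearman")
  }
  list(errors = errors, tests = tests, correlations = cors)
}
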