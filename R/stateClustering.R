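# k-means++ seeding: first centre uniform, subsequent centres with
# probability proportional to squared distance from the nearest chosen centre.
kmeansppSeed <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ], "-")^2)
  if (k > 1L) for (j in 2:k) {
    if (sum(d2) <= 0) {
      # all points coincide with chosen centres; fall back to uniform
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[j, ] <- x[pick, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ], "-")^2))
  }
  centers
}

# One Lloyd run from k-means++ seeds. Empty clusters are re-seeded at the
# point farthest from its nearest centroid.
lloydRun <- function(x, k, maxIter) {
  centers <- kmeansppSeed(x, k)
  labels <- integer(nrow(x))
  for (it in seq_len(maxIter)) {
    d2 <- centroidDist2(x, centers)
    newLabels <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(newLabels == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(x)), newLabels)])
        centers[j, ] <- x[far, ]
        newLabels[far] <- j
      }
    }
    if (identical(newLabels, labels)) break
    labels <- newLabels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
  }
  d2 <- centroidDist2(x, centers)
  labels <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(centers = centers, labels = labels, withinSS = wss)
}

#' k-means clustering with k-means++ seeding
#'
#' Lloyd's algorithm started from k-means++ seeds, repeated `restarts` times;
#' the run with the smallest within-cluster sum of squares is returned.
#' Deterministic for a given `seed`. Empty clusters arising during iteration
#' are re-seeded at the point farthest from its nearest centroid.
#'
#' @param x numeric matrix (rows = points) or vector (treated as 1-D points).
#' @param k number of clusters; the data must contain at least `k` distinct
#'   points.
#' @param seed integer RNG seed (default 0).
#' @param restarts number of k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @return list with `centers` (k x d matrix), `labels` (integer vector in
#'   `1..k`) and `withinSS` (total within-cluster sum of squares).
#' @examples
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 8), 50))
#' km <- kmeansFit(x, k = 2, seed = 1)
#' km$centers
#' @export
kmeansFit <- function(x, k, seed = 0, restarts = 10, maxIter = 300) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
  x <- as.matrix(x)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  nDistinct <- nrow(unique(x))
  if (nDistinct < k)
    stop("degenerate input: fewer distinct points (", nDistinct,
         ") than clusters (", k, ")")
  withSeed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      run <- lloydRun(x, k, maxIter)
      if (is.null(best) || run$withinSS < best$withinSS) best <- run
    }
    best
  })
}

#' Variance criterion of a clustering
#'
#' Explained-variance measure of cluster quality: between-cluster sum of
#' squares over total sum of squares, `1 - SSW/SST`. Approaches 1 as
#' clusters tighten around their centroids; 0 for a single cluster (or when
#' all points coincide, by convention).
#'
#' @param x numeric matrix or vector of points.
#' @param labels integer cluster memberships in `1..nrow(centers)`.
#' @param centers matrix of cluster centroids (one row per cluster).
#' @return numeric in `[0, 1]`.
#' @export
varianceCriterion <- function(x, labels, centers) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1)
  x <- as.matrix(x)
  centers <- as.matrix(centers)
  if (is.null(dim(centers)) || max(labels) > nrow(centers))
    stop("labels inconsistent with centroid count")
  grand <- colMeans(x)
  sst <- sum(sweep(x, 2, grand, "-")^2)
  if (sst <= 0) return(0)
  ssw <- sum((x - centers[labels, , drop = FALSE])^2)
  max(0, min(1, 1 - ssw / sst))
}

#' Fit the two-stage vigilance-state clustering
#'
#' Unsupervised partition of smoothed-log features into the three vigilance
#' states: stage 1 runs 1-D k-means (k = 2) on the EMG r.m.s. axis and maps
#' the higher-centroid cluster to WAKE (muscle tone separates wakefulness
#' from sleep); stage 2 runs 1-D k-means (k = 2) on the delta/theta ratio
#' within the sleep cluster and maps the higher-centroid sub-cluster to NREM
#' (delta-dominant EEG) and the lower to REM (theta-dominant). The mapping
#' is data-driven (by centroid order), never by cluster index.
#'
#' Per-state centroids in standardized 3-D feature space (z-scores using the
#' training sample's per-feature mean and standard deviation) are stored for
#' nearest-centroid scoring of out-of-sample data.
#'
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"` and at
#'   least 30 epochs.
#' @param seed RNG seed for k-means (default 0).
#' @param restarts k-means restarts (default 10).
#' @return A [StateClusterModel-class].
#' @seealso [assignStates()] to score new data.
#' @export
fitStateClusters <- function(feats, seed = 0, restarts = 10) {
  stopifnot(is(feats, "FeatureSeries"))
  if (feats@stage != "smoothed_log")
    stop("fitStateClusters expects smoothed_log features")
  n <- nEpochs(feats)
  if (n < 30) stop("need at least 30 epochs to fit state clusters")
  if (length(unique(feats@emgRMS)) < 2L)
    stop("need >= 2 distinct EMG values to separate Wake from sleep")

  km1 <- kmeansFit(feats@emgRMS, k = 2, seed = seed, restarts = restarts)
  wakeCluster <- which.max(km1$centers[, 1])
  isWake <- km1$labels == wakeCluster

  sleepDt <- feats@dtRatio[!isWake]
  if (length(unique(sleepDt)) < 2L)
    stop("cannot split sleep: fewer than 2 distinct delta/theta values")
  km2 <- kmeansFit(sleepDt, k = 2, seed = seed + 1L, restarts = restarts)
  nremCluster <- which.max(km2$centers[, 1])

  labels <- character(n)
  labels[isWake] <- "WAKE"
  labels[!isWake] <- ifelse(km2$labels == nremCluster, "NREM", "REM")

  m <- featureMatrix(feats)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv <= 0] <- 1
  z <- scale(m, center = mu, scale = sdv)
  centroids <- t(vapply(.STATES, function(s) {
    if (any(labels == s)) colMeans(z[labels == s, , drop = FALSE])
    else rep(NA_real_, 3)
  }, numeric(3)))
  if (anyNA(centroids))
    stop("a vigilance state received no epochs; cannot place its centroid")
  dimnames(centroids) <- list(.STATES, colnames(m))

  new("StateClusterModel",
      emgCentroids = sort(km1$centers[, 1]),
      sleepDtCentroids = sort(km2$centers[, 1]),
      stateCentroids = centroids,
      featureMean = stats::setNames(mu, colnames(m)),
      featureSd = stats::setNames(sdv, colnames(m)),
      stateOrder = .STATES,
      trainLabels = labels)
}

#' Score epochs by nearest state centroid
#'
#' Standardizes the features with the model's training constants and labels
#' each epoch by the nearest of the three state centroids (Euclidean
#' distance in standardized space). Ties are broken toward the state
#' earliest in the WAKE, NREM, REM order.
#'
#' @param model a fitted [StateClusterModel-class].
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @return A [Hypnogram-class] aligned to `feats`.
#' @export
assignStates <- function(model, feats) {
  stopifnot(is(model, "StateClusterModel"), is(feats, "FeatureSeries"))
  if (feats@stage != "smoothed_log")
    stop("assignStates expects smoothed_log features")
  z <- scale(featureMatrix(feats), center = model@featureMean,
             scale = model@featureSd)
  idx <- nearestCentroid(z, model@stateCentroids)
  hypnogram(model@stateOrder[idx], epochS = feats@epochS)
}

#' Fit the observation codebook
#'
#' Runs k-means in standardized 3-D feature space for `M = kmin ... kmax`
#' clusters and returns the smallest M whose variance criterion
#' (between-cluster over total sum of squares) reaches `vcThreshold`. If no
#' M in range reaches the threshold, the largest M is returned with
#' `thresholdMet = FALSE` and a warning.
#'
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @param kmin,kmax codebook size range (defaults 3 and 15).
#' @param vcThreshold variance-criterion target (default 0.90).
#' @param seed RNG seed (default 0).
#' @param restarts k-means restarts per M (default 10).
#' @return An [ObservationCodebook-class].
#' @export
fitCodebook <- function(feats, kmin = 3, kmax = 15, vcThreshold = 0.90,
                        seed = 0, restarts = 10) {
  stopifnot(is(feats, "FeatureSeries"))
  if (feats@stage != "smoothed_log")
    stop("fitCodebook expects smoothed_log features")
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  stopifnot(kmin >= 3L, kmax <= 15L, kmin <= kmax)
  m <- featureMatrix(feats)
  nDistinct <- nrow(unique(m))
  if (nDistinct < kmin)
    stop("degenerate input: fewer distinct points than kmin")
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv <= 0] <- 1
  z <- scale(m, center = mu, scale = sdv)

  chosen <- NULL
  for (M in kmin:kmax) {
    if (nDistinct < M) break
    km <- kmeansFit(z, k = M, seed = seed + M, restarts = restarts)
    vc <- varianceCriterion(z, km$labels, km$centers)
    chosen <- list(M = M, centers = km$centers, vc = vc)
    if (vc >= vcThreshold) break
  }
  met <- chosen$vc >= vcThreshold
  if (!met)
    warning("variance criterion ", vcThreshold, " not reached by M = ",
            chosen$M, " clusters (VC = ", signif(chosen$vc, 3), ")")
  new("ObservationCodebook",
      centroids = unname(chosen$centers), M = as.integer(chosen$M),
      vc = chosen$vc, vcThreshold = vcThreshold, thresholdMet = met,
      featureMean = stats::setNames(mu, colnames(m)),
      featureSd = stats::setNames(sdv, colnames(m)))
}

#' Quantize features onto a codebook
#'
#' Maps each epoch's feature vector (standardized with the codebook's
#' constants) to the index of the nearest codebook centroid. Ties go to the
#' lowest index.
#'
#' @param codebook an [ObservationCodebook-class].
#' @param feats a [FeatureSeries-class] with `stage = "smoothed_log"`.
#' @return integer vector of symbols in `1..M`, one per epoch.
#' @export
quantizeFeatures <- function(codebook, feats) {
  stopifnot(is(codebook, "ObservationCodebook"), is(feats, "FeatureSeries"))
  if (feats@stage != "smoothed_log")
    stop("quantizeFeatures expects smoothed_log features")
  z <- scale(featureMatrix(feats), center = codebook@featureMean,
             scale = codebook@featureSd)
  nearestCentroid(z, codebook@centroids)
}
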