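test_that("kmeansFit handles degenerate and well-separated cases", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  km1 <- kmeansFit(x, 1, seed = 0)
  expect_equal(as.numeric(km1$centers), colMeans(x))
  expect_equal(km1$withinSS, sum(sweep(x, 2, colMeans(x))^2))

  pm <- rbind(matrix(0, 30, 3), matrix(10, 25, 3))
  km2 <- kmeansFit(pm, 2, seed = 1)
  expect_equal(sort(km2$centers[, 1]), c(0, 10))
  expect_equal(km2$withinSS, 0)

  expect_error(kmeansFit(matrix(1, 10, 2), 2), "degenerate")
})

test_that("kmeansFit separates two 1-D Gaussians like the true-means rule", {
  set.seed(21)
  comp <- rep(1:2, each = 100)
  x <- rnorm(200, mean = c(0, 8)[comp], sd = 1)
  km <- kmeansFit(x, 2, seed = 4)
  # oracle: assign each point to the nearer of the generating means 0 and 8
  oracle <- ifelse(abs(x - 0) <= abs(x - 8), 1L, 2L)
  lowCluster <- which.min(km$centers[, 1])
  pred <- ifelse(km$labels == lowCluster, 1L, 2L)
  expect_gte(mean(pred == oracle), 0.99)
  expect_gte(mean(pred == comp), 0.99)
})

test_that("kmeansFit is deterministic given a seed", {
  set.seed(9)
  x <- matrix(rnorm(300), 100, 3)
  a <- kmeansFit(x, 4, seed = 123)
  b <- kmeansFit(x, 4, seed = 123)
  expect_identical(a, b)
})

test_that("varianceCriterion is explained variance", {
  pm <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  labs <- rep(1:2, each = 10)
  centers <- rbind(c(0, 0), c(5, 5))
  expect_equal(varianceCriterion(pm, labs, centers), 1)

  set.seed(5)
  x <- matrix(rnorm(90), 30, 3)
  expect_equal(varianceCriterion(x, rep(1L, 30), t(colMeans(x))), 0)

  # random labelling of one blob: equals 1 - SSW/SST by direct summation
  labs3 <- sample(1:3, 30, replace = TRUE)
  cent <- t(sapply(1:3, function(j) colMeans(x[labs3 == j, , drop = FALSE])))
  ssw <- sum(sapply(1:3, function(j)
    sum(sweep(x[labs3 == j, , drop = FALSE], 2, cent[j, ])^2)))
  sst <- sum(sweep(x, 2, colMeans(x))^2)
  expect_equal(varianceCriterion(x, labs3, cent), 1 - ssw / sst,
               tolerance = 1e-12)

  expect_equal(varianceCriterion(matrix(1, 20, 3), rep(1:2, 10),
                                 matrix(1, 2, 3)), 0)
})

test_that("two-stage clustering recovers generating states on separable data", {
  fx <- makeSeparableFixture(T = 1200, seed = 31)
  model <- fitStateClusters(fx$f)
  expect_gte(mean(model@trainLabels == stateLabels(fx$h)), 0.99)
  # WAKE maps to the larger EMG centroid, NREM to the larger dt centroid
  expect_true(model@stateCentroids["WAKE", "emg_rms"] >
              model@stateCentroids["NREM", "emg_rms"])
  expect_true(model@stateCentroids["NREM", "dt_ratio"] >
              model@stateCentroids["REM", "dt_ratio"])
})

test_that("state mapping is data-driven, not index-driven", {
  fx <- makeSeparableFixture(T = 900, seed = 32)
  model <- fitStateClusters(fx$f)
  # negate the EMG axis: the formerly-sleep epochs now carry the higher EMG
  # values, so WAKE must follow the data to the other cluster
  flipped <- featureSeries(-fx$f@emgRMS, fx$f@dtRatio, fx$f@hlRatio,
                           epochS = 4, stage = "smoothed_log")
  mflip <- fitStateClusters(flipped)
  wasWake <- stateLabels(fx$h) == "WAKE"
  expect_gte(mean(mflip@trainLabels[wasWake] != "WAKE"), 0.99)
  expect_gte(mean(mflip@trainLabels[!wasWake] == "WAKE"), 0.98)
})

test_that("assignStates is nearest-centroid with WAKE-first tie-breaking", {
  fx <- makeSeparableFixture(T = 1000, seed = 33)
  model <- fitStateClusters(fx$f)
  h <- assignStates(model, fx$f)
  # oracle: recompute nearest centroid by exhaustive distance comparison
  z <- scale(featureMatrix(fx$f), center = model@featureMean,
             scale = model@featureSd)
  d <- sapply(1:3, function(i)
    rowSums(sweep(z, 2, model@stateCentroids[i, ])^2))
  oracle <- STATES[apply(d, 1, which.min)]
  expect_identical(stateLabels(h), oracle)
  expect_gte(mean(stateLabels(h) == model@trainLabels), 0.95)

  # symmetric hand-built model: point at a centroid, and an equidistant point
  m2 <- model
  m2@featureMean <- c(emg_rms = 0, dt_ratio = 0, hl_ratio = 0)
  m2@featureSd <- c(emg_rms = 1, dt_ratio = 1, hl_ratio = 1)
  m2@stateCentroids <- diag(3)
  dimnames(m2@stateCentroids) <- dimnames(model@stateCentroids)
  atWake <- featureSeries(1, 0, 0, stage = "smoothed_log")
  equidist <- featureSeries(0, 0, 0, stage = "smoothed_log")
  expect_identical(stateLabels(assignStates(m2, atWake)), "WAKE")
  expect_identical(stateLabels(assignStates(m2, equidist)), "WAKE")
})

test_that("fitStateClusters rejects inadequate inputs", {
  small <- featureSeries(rnorm(10), rnorm(10), rnorm(10),
                         stage = "smoothed_log")
  expect_error(fitStateClusters(small), "at least 30")
  raw <- featureSeries(rexp(50) + 1, rexp(50) + 1, rexp(50) + 1,
                       stage = "raw")
  expect_error(fitStateClusters(raw), "smoothed_log")
})

test_that("codebook selection picks the smallest M reaching the criterion", {
  # three point-mass clusters -> M = 3 with VC = 1
  pm <- featureSeries(rep(c(0, 5, 10), each = 20) + rep(c(0, 1e-9), 30),
                      rep(c(0, 5, 10), each = 20),
                      rep(c(0, 5, 10), each = 20), stage = "smoothed_log")
  cb <- fitCodebook(pm, seed = 1)
  expect_identical(codebookSize(cb), 3L)
  expect_gt(cb@vc, 0.999)
  expect_true(cb@thresholdMet)

  # 7 Gaussians whose means sit well-spread on a sphere of radius 7 with
  # unit-scale spread 0.8 (pairwise separations >= 10 sd): merging any two
  # clusters costs more than 10% of the total sum of squares, so the scan
  # must go all the way to M = 7
  set.seed(44)
  ang <- 2 * pi * (0:4) / 5
  centers <- rbind(c(0, 0, 7), c(0, 0, -7),
                   cbind(7 * cos(ang), 7 * sin(ang), 0))
  comp <- rep(1:7, each = 40)
  pts <- centers[comp, ] + 0.8 * matrix(rnorm(280 * 3), 280, 3)
  f7 <- featureSeries(pts[, 1], pts[, 2], pts[, 3], stage = "smoothed_log")
  cb7 <- fitCodebook(f7, seed = 2)
  expect_identical(codebookSize(cb7), 7L)
  z <- scale(pts)
  for (M in 3:7) {
    km <- kmeansFit(z, M, seed = 2 + M)
    vcDirect <- {
      ssw <- sum((z - km$centers[km$labels, ])^2)
      1 - ssw / sum(scale(z, scale = FALSE)^2)
    }
    expect_equal(varianceCriterion(z, km$labels, km$centers), vcDirect,
                 tolerance = 1e-10)
    if (M < 7) expect_lt(vcDirect, 0.90)
  }
})

test_that("an unreachable criterion returns kmax with a warning", {
  set.seed(45)
  blob <- matrix(rnorm(3 * 400), 400, 3)
  fb <- featureSeries(blob[, 1], blob[, 2], blob[, 3],
                      stage = "smoothed_log")
  expect_warning(cb <- fitCodebook(fb, seed = 3), "not reached")
  expect_identical(codebookSize(cb), 15L)
  expect_false(cb@thresholdMet)
  expect_lt(cb@vc, 0.90)
})

test_that("quantizeFeatures maps to the nearest centroid with low-index ties", {
  fx <- makeSeparableFixture(T = 600, seed = 34)
  cb <- fitCodebook(fx$f, seed = 5)
  sym <- quantizeFeatures(cb, fx$f)
  expect_true(all(sym >= 1L & sym <= codebookSize(cb)))
  # exhaustive distance comparison oracle
  z <- scale(featureMatrix(fx$f), center = cb@featureMean,
             scale = cb@featureSd)
  d <- sapply(seq_len(cb@M), function(j)
    rowSums(sweep(z, 2, cb@centroids[j, ])^2))
  expect_identical(sym, max.col(-d, ties.method = "first"))

  # each centroid maps to its own index; an equidistant point to the lower
  toFeat <- function(zrow) {
    v <- zrow * cb@featureSd + cb@featureMean
    featureSeries(v[1], v[2], v[3], stage = "smoothed_log")
  }
  for (j in seq_len(cb@M))
    expect_identical(quantizeFeatures(cb, toFeat(cb@centroids[j, ])), j)
  # tie on a hand-built codebook where the midpoint of centroids 2 and 3 is
  # not closer to any other centroid
  cbTie <- new("ObservationCodebook",
               centroids = rbind(c(10, 10, 10), c(0, 0, 0), c(2, 0, 0),
                                 c(-6, -6, -6)),
               M = 4L, vc = 0.95, vcThreshold = 0.9, thresholdMet = TRUE,
               featureMean = c(emg_rms = 0, dt_ratio = 0, hl_ratio = 0),
               featureSd = c(emg_rms = 1, dt_ratio = 1, hl_ratio = 1))
  tiePoint <- featureSeries(1, 0, 0, stage = "smoothed_log")
  expect_identical(quantizeFeatures(cbTie, tiePoint), 2L)
})
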