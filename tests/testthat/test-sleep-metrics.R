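test_that("bouts are maximal runs that tile the hypnogram", {
  b <- bouts(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM",
                         "REM", "WAKE")))
  expect_identical(b$state, c("WAKE", "NREM", "REM", "WAKE"))
  expect_identical(b$start_epoch, c(0L, 2L, 5L, 6L))
  expect_identical(b$length_epochs, c(2L, 3L, 1L, 1L))

  allN <- bouts(hypnogram(rep("NREM", 37)))
  expect_identical(nrow(allN), 1L)
  expect_identical(allN$length_epochs, 37L)

  alt <- bouts(hypnogram(rep(c("WAKE", "NREM"), 2)))
  expect_identical(nrow(alt), 4L)
  expect_true(all(alt$length_epochs == 1L))

  # property: tiling on random hypnograms
  set.seed(61)
  for (i in 1:20) {
    T <- sample(1:200, 1)
    h <- hypnogram(sample(STATES, T, replace = TRUE))
    b <- bouts(h)
    expect_identical(sum(b$length_epochs), T)
    expect_true(all(diff(match(b$state, STATES)) != 0) || nrow(b) == 1L)
    expect_identical(b$start_epoch,
                     cumsum(c(0L, b$length_epochs[-nrow(b)])))
  }
})

test_that("sleepMetrics reproduces hand-computed values", {
  m <- sleepMetrics(hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "NREM",
                                "REM", "WAKE"), epochS = 4))
  expect_equal(m$percent_time, c(3/7, 3/7, 1/7) * 100, tolerance = 1e-12)
  expect_identical(m$n_bouts, c(2L, 1L, 1L))
  expect_equal(m$mean_bout_s, c(6, 12, 4))

  allW <- sleepMetrics(hypnogram(rep("WAKE", 25), epochS = 4))
  expect_equal(allW$percent_time, c(100, 0, 0))
  expect_identical(allW$n_bouts, c(1L, 0L, 0L))
  expect_equal(allW$mean_bout_s[1], 100)
  expect_true(all(is.na(allW$mean_bout_s[2:3])))   # absent states: NA, not 0

  # reversal symmetry
  set.seed(62)
  lab <- sample(STATES, 100, replace = TRUE)
  m1 <- sleepMetrics(hypnogram(lab))
  m2 <- sleepMetrics(hypnogram(rev(lab)))
  expect_equal(m1, m2)
})

test_that("percent time sums to 100 and time is conserved across bouts", {
  set.seed(63)
  for (i in 1:20) {
    T <- sample(2:500, 1)
    es <- sample(c(2, 4, 10), 1)
    h <- hypnogram(sample(STATES, T, replace = TRUE,
                          prob = c(0.5, 0.4, 0.1)), epochS = es)
    m <- sleepMetrics(h)
    expect_equal(sum(m$percent_time), 100, tolerance = 1e-9)
    ok <- m$n_bouts > 0
    expect_equal(sum(m$n_bouts[ok] * m$mean_bout_s[ok]), T * es,
                 tolerance = 1e-9)
  }
})

test_that("agreement reproduces hand-counted confusion statistics", {
  h <- hypnogram(sample(STATES, 50, replace = TRUE))
  perfect <- agreement(h, h)
  expect_equal(perfect$overall, 100)
  expect_true(all(stats::na.omit(perfect$perState$sensitivity) == 100))
  expect_true(all(stats::na.omit(perfect$perState$specificity) == 100))

  ref <- hypnogram(c("WAKE", "WAKE", "NREM", "REM"))
  pred <- hypnogram(c("WAKE", "NREM", "NREM", "REM"))
  ag <- agreement(ref, pred)
  expect_equal(ag$overall, 75)
  expect_equal(ag$perState$sensitivity[1], 50)    # WAKE: 1 of 2
  expect_equal(ag$perState$specificity[1], 100)
  expect_equal(ag$perState$sensitivity[2], 100)   # NREM: 1 of 1
  expect_equal(ag$perState$specificity[2], 100 * 2/3)
  expect_equal(sum(ag$confusion), 4)

  expect_error(agreement(ref, hypnogram(c("WAKE", "WAKE"))), "alignment")
})

test_that("relabeling both hypnograms by one permutation permutes the confusion", {
  set.seed(64)
  ref <- sample(STATES, 200, replace = TRUE)
  pred <- sample(STATES, 200, replace = TRUE)
  ag <- agreement(hypnogram(ref), hypnogram(pred))
  permMap <- c(WAKE = "NREM", NREM = "REM", REM = "WAKE")
  agP <- agreement(hypnogram(unname(permMap[ref])),
                   hypnogram(unname(permMap[pred])))
  expect_equal(agP$overall, ag$overall)
  expect_equal(agP$confusion[permMap, permMap],
               matrix(ag$confusion, 3, 3,
                      dimnames = list(permMap, permMap)),
               ignore_attr = TRUE)
})

test_that("compareScorers yields zero errors and rho = 1 for perfect scorers", {
  set.seed(65)
  refs <- lapply(1:5, function(i)
    simulateHypnogram(lightChain(), T = 300, seed = 70 + i))
  cmp <- compareScorers(refs, refs, refs)
  expect_true(all(cmp$errors$error == 0, na.rm = TRUE))
  rho <- cmp$correlations$spearman_rho
  expect_true(all(abs(stats::na.omit(rho) - 1) < 1e-12))
  expect_error(compareScorers(refs[1], refs[1], refs[1]), "at least 2")
})

test_that("the Wilcoxon machinery matches exhaustive sign-flip enumeration", {
  d <- c(1, 2, 3, -4, 5)
  wt <- suppressWarnings(stats::wilcox.test(d, mu = 0))
  expect_equal(unname(wt$statistic), 11)   # rank-sum of positive differences

  # exact two-sided p by enumerating all 2^5 sign patterns
  ranks <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 5)))
  W <- signs %*% ranks
  w0 <- sum(ranks[d > 0])
  pExact <- mean(pmin(W, sum(ranks) - W) <= min(w0, sum(ranks) - w0))
  expect_equal(wt$p.value, pExact, tolerance = 1e-12)

  expect_equal(stats::cor(1:3, 3:1, method = "spearman"), -1)
})
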