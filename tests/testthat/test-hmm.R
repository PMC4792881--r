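test_that("initHMM counts transitions and emissions by hand-checkable rules", {
  # W,W,N,N,W: transitions W->W, W->N, N->N, N->W
  states <- hypnogram(c("WAKE", "WAKE", "NREM", "NREM", "WAKE"))
  expect_warning(
    hmm <- initHMM(symbols = c(1L, 1L, 2L, 2L, 1L), states, codebook = 2L,
                   floorProb = 0),
    "absent")
  expect_equal(hmm@A["WAKE", ], c(WAKE = 1/2, NREM = 1/2, REM = 0))
  expect_equal(hmm@A["NREM", ], c(WAKE = 1/2, NREM = 1/2, REM = 0))
  # REM unseen: uniform row (flooring off, so exactly 1/3)
  expect_equal(unname(hmm@A["REM", ]), rep(1/3, 3))

  allW <- hypnogram(rep("WAKE", 6))
  expect_warning(hw <- initHMM(rep(1L, 6), allW, 3L, floorProb = 0),
                 "absent")
  expect_equal(unname(hw@B[1, ]), c(1, 0, 0))   # point mass at symbol 1
})

test_that("initHMM floors probabilities and keeps rows stochastic", {
  states <- hypnogram(rep(c("WAKE", "NREM", "REM"), each = 30))
  sym <- rep(c(1L, 2L, 3L), each = 30)
  hmm <- initHMM(sym, states, 4L)
  # floored entries sit at floorProb up to the renormalization factor
  expect_true(all(hmm@A >= 0.99e-6))
  expect_true(all(hmm@B >= 0.99e-6))
  expect_equal(unname(rowSums(hmm@A)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(rowSums(hmm@B)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sum(hmm@pi), 1, tolerance = 1e-12)
  # pi defaults to the stationary distribution of A
  expect_equal(hmm@pi, as.numeric(hmm@pi %*% hmm@A), tolerance = 1e-9)
  # alternative: first-state indicator (floored)
  hmmF <- initHMM(sym, states, 4L, piMode = "first")
  expect_gt(hmmF@pi[1], 0.99)
})

test_that("estimated transition matrix approaches the generator on long chains", {
  gen <- hmmModel(c(0.3, 0.6, 0.1),
                  matrix(c(0.92, 0.06, 0.02,
                           0.03, 0.93, 0.04,
                           0.08, 0.07, 0.85), 3, 3, byrow = TRUE),
                  diag(3) * 0.85 + 0.05)
  sm <- sampleHMM(gen, T = 20000, seed = 77)
  est <- initHMM(sm$symbols, sm$hypnogram, 3L)
  expect_lt(max(abs(est@A - gen@A)), 0.02)
})

test_that("forward log-likelihood matches closed forms and brute-force enumeration", {
  # T = 1, uniform pi and B: log(1/M)
  for (M in c(3L, 5L)) {
    hmmU <- hmmModel(rep(1/3, 3), matrix(1/3, 3, 3), matrix(1/M, 3, M))
    expect_equal(forwardLoglik(hmmU, 2L), log(1/M), tolerance = 1e-12)
  }

  # deterministic cycle with consistent symbols: log pi of the start state
  P <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  hmmC <- hmmModel(c(0.5, 0.3, 0.2), P, diag(3))
  sym <- c(1L, 2L, 3L, 1L, 2L)
  expect_equal(forwardLoglik(hmmC, sym), log(0.5), tolerance = 1e-12)

  # brute-force path-sum oracle on random instances
  set.seed(101)
  for (i in 1:25) {
    M <- sample(2:5, 1)
    T <- sample(2:8, 1)
    hmm <- randomHMM(M, seed = 1000 + i)
    sym <- sample.int(M, T, replace = TRUE)
    expect_equal(forwardLoglik(hmm, sym),
                 bruteLoglik(hmm@pi, hmm@A, hmm@B, sym),
                 tolerance = 1e-10)
  }

  hmm3 <- randomHMM(3, seed = 1)
  expect_error(forwardLoglik(hmm3, c(1L, 4L)), "invalid symbol")
})

test_that("Viterbi matches exhaustive maximization and breaks ties toward WAKE", {
  # unambiguous emissions: the decoded path reads off the symbols
  ergodicA <- matrix(c(0.8, 0.15, 0.05, 0.2, 0.7, 0.1, 0.3, 0.3, 0.4),
                     3, 3, byrow = TRUE)
  hmmI <- hmmModel(rep(1/3, 3), ergodicA, diag(3))
  sym <- c(1L, 1L, 2L, 3L, 2L, 1L)
  vt <- viterbiDecode(hmmI, sym)
  expect_identical(stateLabels(vt$hypnogram), STATES[sym])

  # all-uniform model: every path tied, tie rule gives all-WAKE
  hmmU <- hmmModel(rep(1/3, 3), matrix(1/3, 3, 3), matrix(1/4, 3, 4))
  vtU <- viterbiDecode(hmmU, c(1L, 2L, 3L, 4L))
  expect_identical(unique(stateLabels(vtU$hypnogram)), "WAKE")

  # brute-force oracle over all 3^T paths
  set.seed(202)
  for (i in 1:40) {
    M <- sample(2:5, 1)
    T <- sample(2:8, 1)
    hmm <- randomHMM(M, seed = 2000 + i)
    sym <- sample.int(M, T, replace = TRUE)
    bf <- bruteViterbi(hmm@pi, hmm@A, hmm@B, sym)
    vt <- viterbiDecode(hmm, sym)
    expect_equal(vt$logProb, bf$logProb, tolerance = 1e-10)
    if (nrow(bf$argmax) == 1L)
      expect_identical(match(stateLabels(vt$hypnogram), STATES),
                       as.integer(bf$argmax[1, ]))
    # returned log-probability equals the decoded path's own log-probability
    path <- match(stateLabels(vt$hypnogram), STATES)
    expect_equal(vt$logProb,
                 log(pathProb(hmm@pi, hmm@A, hmm@B, path, sym)),
                 tolerance = 1e-10)
  }
})

test_that("Baum-Welch increases likelihood and preserves stochasticity", {
  set.seed(303)
  for (i in 1:5) {
    hmm <- randomHMM(4, seed = 3000 + i)
    sym <- sample.int(4, 200, replace = TRUE)
    bw <- baumWelch(hmm, sym, maxIter = 50)
    expect_true(all(diff(bw$logLik) >= -1e-9))
    m <- bw$model
    expect_equal(sum(m@pi), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(m@A)), rep(1, 3), tolerance = 1e-12)
    expect_equal(unname(rowSums(m@B)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(m@A > 0) && all(m@B > 0) && all(m@pi > 0))
  }
})

test_that("Baum-Welch stays near the generator when started at it", {
  gen <- hmmModel(c(0.34, 0.55, 0.11),
                  matrix(c(0.95, 0.04, 0.01,
                           0.02, 0.95, 0.03,
                           0.06, 0.05, 0.89), 3, 3, byrow = TRUE),
                  matrix(c(0.85, 0.05, 0.05, 0.05,
                           0.05, 0.85, 0.05, 0.05,
                           0.05, 0.05, 0.45, 0.45), 3, 4, byrow = TRUE))
  sm <- sampleHMM(gen, T = 10000, seed = 88)
  bw <- baumWelch(gen, sm$symbols)
  expect_lt(max(abs(bw$model@A - gen@A)), 0.02)
  expect_lt(max(abs(bw$model@B - gen@B)), 0.02)
})

test_that("constant symbol sequences drive B toward a point mass", {
  hmm <- randomHMM(3, seed = 99)
  bw <- baumWelch(hmm, rep(2L, 300))
  expect_true(all(bw$model@B[, 2] >= 0.99))
})

test_that("sampleHMM is seed-deterministic and matches stationary symbol frequencies", {
  gen <- hmmModel(c(0.3, 0.5, 0.2),
                  matrix(c(0.9, 0.08, 0.02,
                           0.05, 0.9, 0.05,
                           0.1, 0.1, 0.8), 3, 3, byrow = TRUE),
                  matrix(c(0.7, 0.2, 0.1,
                           0.1, 0.8, 0.1,
                           0.2, 0.2, 0.6), 3, 3, byrow = TRUE))
  a <- sampleHMM(gen, T = 500, seed = 5)
  b <- sampleHMM(gen, T = 500, seed = 5)
  expect_identical(a, b)
  d <- sampleHMM(gen, T = 500, seed = 6)
  expect_false(identical(a$symbols, d$symbols))

  # chain-weighted mixture of B rows as oracle for long-run symbol frequency
  sm <- sampleHMM(gen, T = 50000, seed = 7)
  statW <- stationaryDistribution(gen@A)
  expected <- as.numeric(statW %*% gen@B)
  observed <- tabulate(sm$symbols, 3) / 50000
  expect_lt(max(abs(observed - expected)), 0.01)

  # A = identity, pi a point mass: constant path
  idHMM <- hmmModel(c(0, 1, 0), diag(3), matrix(1/3, 3, 3))
  expect_identical(unique(stateLabels(sampleHMM(idHMM, 50, seed = 1)$hypnogram)),
                   "NREM")
})

test_that("permuting generator states permutes the decoded labels identically", {
  perm <- c(2L, 3L, 1L)   # new index of each old state
  gen <- hmmModel(c(0.2, 0.5, 0.3),
                  matrix(c(0.85, 0.1, 0.05,
                           0.05, 0.9, 0.05,
                           0.15, 0.05, 0.8), 3, 3, byrow = TRUE),
                  matrix(c(0.8, 0.1, 0.05, 0.05,
                           0.05, 0.8, 0.1, 0.05,
                           0.05, 0.05, 0.1, 0.8), 3, 4, byrow = TRUE))
  inv <- order(perm)
  genP <- hmmModel(gen@pi[inv], gen@A[inv, inv], gen@B[inv, ])
  sym <- sampleHMM(gen, T = 400, seed = 13)$symbols
  p1 <- match(stateLabels(viterbiDecode(gen, sym)$hypnogram), STATES)
  p2 <- match(stateLabels(viterbiDecode(genP, sym)$hypnogram), STATES)
  expect_identical(perm[p1], p2)
})
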