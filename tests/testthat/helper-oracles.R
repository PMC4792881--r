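# Independent oracles used across the suite. These deliberately avoid the
# package's forward/Viterbi/k-means code paths.

STATES <- c("WAKE", "NREM", "REM")

# Probability of one state path under (pi, A, B) for a symbol sequence.
pathProb <- function(pi, A, B, path, symbols) {
  p <- pi[path[1]] * B[path[1], symbols[1]]
  if (length(path) > 1L) for (t in 2:length(path))
    p <- p * A[path[t - 1], path[t]] * B[path[t], symbols[t]]
  p
}

# All 3^T state paths as a matrix (rows = paths).
allPaths <- function(T) {
  as.matrix(expand.grid(rep(list(1:3), T)))
}

# log P(symbols) by exhaustive path-sum enumeration.
bruteLoglik <- function(pi, A, B, symbols) {
  paths <- allPaths(length(symbols))
  log(sum(apply(paths, 1, pathProb, pi = pi, A = A, B = B,
                symbols = symbols)))
}

# Exhaustive maximization over state paths: best log-probability and the
# set of argmax paths (for tie-aware comparison).
bruteViterbi <- function(pi, A, B, symbols) {
  paths <- allPaths(length(symbols))
  lp <- log(apply(paths, 1, pathProb, pi = pi, A = A, B = B,
                  symbols = symbols))
  best <- max(lp)
  list(logProb = best,
       argmax = paths[abs(lp - best) < 1e-12, , drop = FALSE])
}

# Random valid HMM with Dirichlet(1) rows.
randomHMM <- function(M, seed) {
  set.seed(seed)
  normRows <- function(m) m / rowSums(m)
  A <- normRows(matrix(rgamma(9, 1), 3, 3))
  B <- normRows(matrix(rgamma(3 * M, 1), 3, M))
  p <- rgamma(3, 1); p <- p / sum(p)
  hmmModel(p, A, B)
}

# Squared zero-phase magnitude response of the Butterworth bandpass used by
# bandpass(): |H(e^{-i w})|^2 evaluated directly from the filter polynomial
# coefficients (no time-domain filtering involved).
zeroPhaseGain <- function(freq, fs, lo, hi, order = 3) {
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * freq / fs
  z <- exp(-1i * w)
  polyEval <- function(coefs) sum(coefs * z^(seq_along(coefs) - 1))
  Mod(polyEval(bf$b) / polyEval(bf$a))^2
}

rms <- function(x) sqrt(mean(x^2))

# Separable three-state fixture: hypnogram plus features drawn from the
# default preset.
makeSeparableFixture <- function(T = 1500, seed = 11, noiseScale = 1) {
  h <- simulateHypnogram(lightChain(), T = T, seed = seed)
  f <- simulateFeatures(h, defaultStateFeatureModel(noiseScale), seed = seed + 1)
  list(h = h, f = f)
}
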