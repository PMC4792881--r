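# Internal helpers shared across modules.

# Evaluate expr under a private RNG stream, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Smallest admissible power / probability-before-log value (squared-microvolt
# units); keeps outputs finite on silent channels.
.POWER_FLOOR <- 1e-12

#' Stationary distribution of a stochastic matrix
#'
#' Solves \eqn{\pi A = \pi, \sum_i \pi_i = 1} for a row-stochastic transition
#' matrix, the long-run state occupancy of the chain.
#'
#' @param A row-stochastic square matrix.
#' @return numeric probability vector.
#' @examples
#' A <- matrix(c(.9, .1, 0, .05, .9, .05, .1, .1, .8), 3, 3, byrow = TRUE)
#' stationaryDistribution(A)
#' @export
stationaryDistribution <- function(A) {
  A <- as.matrix(A)
  k <- nrow(A)
  stopifnot(ncol(A) == k, all(A >= 0), all(abs(rowSums(A) - 1) < 1e-8))
  # (A' - I) pi = 0 with sum constraint appended; least squares is robust to
  # the rank deficiency of the homogeneous system
  M <- rbind(t(A) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  p <- as.numeric(qr.solve(M, b))
  p[p < 0] <- 0
  p / sum(p)
}

# Row-wise floor-and-renormalize for probability matrices.
floorRows <- function(P, floor) {
  P <- pmax(P, floor)
  P / rowSums(P)
}

floorVec <- function(p, floor) {
  p <- pmax(p, floor)
  p / sum(p)
}

# Squared Euclidean distances from each row of x to each row of centroids,
# computed by direct differencing (exact ties on symmetric inputs).
centroidDist2 <- function(x, centroids) {
  x <- as.matrix(x)
  centroids <- as.matrix(centroids)
  d2 <- matrix(0, nrow(x), nrow(centroids))
  for (j in seq_len(nrow(centroids))) {
    diff <- sweep(x, 2, centroids[j, ], "-")
    d2[, j] <- rowSums(diff^2)
  }
  d2
}

# Nearest row of `centroids` for each row of `x`; ties -> lowest index.
nearestCentroid <- function(x, centroids) {
  d2 <- centroidDist2(x, centroids)
  max.col(-d2, ties.method = "first")
}
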