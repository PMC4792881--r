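#' @useDynLib sleepHMM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.checkSymbols <- function(symbols, M) {
  symbols <- as.integer(symbols)
  if (length(symbols) == 0L) stop("empty symbol sequence")
  if (any(symbols < 1L) || any(symbols > M))
    stop("invalid symbol: symbols must lie in 1..M (M = ", M, ")")
  symbols
}

.stateIndex <- function(h) {
  match(h@labels, .STATES)
}

#' Initialize a discretized-observation HMM from cluster memberships
#'
#' Builds the initial-guess HMM from a scored training sequence: the
#' transition matrix `A` from relative frequencies of state transitions in
#' the hypnogram, and the emission matrix `B` from relative frequencies of
#' each codebook symbol within each state. All entries are floored at
#' `floorProb` and rows renormalized so out-of-sample sequences containing
#' unseen symbols or transitions retain nonzero likelihood. A state absent
#' from the training labels receives uniform rows with a warning.
#'
#' The initial distribution `pi` defaults to the stationary distribution of
#' `A` (appropriate for long recordings); `piMode = "first"` instead puts
#' unit mass (pre-flooring) on the first observed state.
#'
#' @param symbols integer codebook symbols in `1..M`, one per epoch.
#' @param states a [Hypnogram-class] of the same length (the two-stage
#'   k-means memberships during unsupervised fitting).
#' @param codebook the [ObservationCodebook-class] that produced `symbols`,
#'   or an integer M for a free-standing model.
#' @param floorProb probability floor (default `1e-6`).
#' @param piMode `"stationary"` (default) or `"first"`.
#' @return A [DiscretizedHMM-class].
#' @export
initHMM <- function(symbols, states, codebook, floorProb = 1e-6,
                    piMode = c("stationary", "first")) {
  piMode <- match.arg(piMode)
  stopifnot(is(states, "Hypnogram"))
  cb <- NULL
  if (is(codebook, "ObservationCodebook")) {
    cb <- codebook
    M <- codebook@M
  } else {
    M <- as.integer(codebook)
  }
  symbols <- .checkSymbols(symbols, M)
  if (length(symbols) != nEpochs(states))
    stop("symbols and states must have equal length")
  if (length(symbols) < 2L) stop("need at least 2 epochs")

  si <- .stateIndex(states)
  A <- matrix(0, 3, 3)
  trans <- table(factor(si[-length(si)], levels = 1:3),
                 factor(si[-1], levels = 1:3))
  A[] <- as.numeric(trans)
  Bc <- table(factor(si, levels = 1:3), factor(symbols, levels = 1:M))
  B <- matrix(as.numeric(Bc), 3, M)

  absent <- tabulate(si, 3L) == 0L
  if (any(absent)) {
    warning("state(s) absent from training labels: ",
            paste(.STATES[absent], collapse = ", "),
            "; using uniform rows")
    A[absent, ] <- 1 / 3
    B[absent, ] <- 1 / M
  }
  rs <- rowSums(A)
  # a state observed only at the final epoch has no outgoing transition
  A[rs == 0, ] <- 1 / 3
  A <- A / rowSums(A)
  B <- B / rowSums(B)

  A <- floorRows(A, floorProb)
  B <- floorRows(B, floorProb)
  p <- if (piMode == "stationary") {
    stationaryDistribution(A)
  } else {
    p0 <- numeric(3); p0[si[1]] <- 1
    floorVec(p0, floorProb)
  }
  hmmModel(p, A, B, codebook = cb)
}

#' Log-likelihood of a symbol sequence under an HMM
#'
#' Exact `log P(symbols | model)` via the scaled forward algorithm.
#'
#' @param hmm a [DiscretizedHMM-class].
#' @param symbols integer symbols in `1..M`.
#' @return log-likelihood scalar.
#' @export
forwardLoglik <- function(hmm, symbols) {
  stopifnot(is(hmm, "DiscretizedHMM"))
  symbols <- .checkSymbols(symbols, ncol(hmm@B))
  .forward_cpp(hmm@pi, hmm@A, hmm@B, symbols - 1L)$logLik
}

#' Baum-Welch refinement of a discretized-observation HMM
#'
#' Maximum-likelihood refinement by expectation-maximization: a scaled
#' forward-backward E-step followed by the closed-form M-step, iterated
#' until the relative log-likelihood improvement falls below `tol` or
#' `maxIter` is reached. `pi`, the rows of `A` and the rows of `B` are all
#' re-estimated, floored at `floorProb` and renormalized after each M-step.
#' The per-iteration log-likelihood trace (evaluated at the parameters in
#' force at the start of each iteration) is non-decreasing up to numerical
#' slack.
#'
#' @param hmm a [DiscretizedHMM-class] initial guess.
#' @param symbols integer symbols in `1..M`, length >= 2.
#' @param tol relative improvement tolerance (default `1e-6`).
#' @param maxIter iteration cap (default 500).
#' @param floorProb probability floor (default `1e-6`).
#' @return list with `model` (refined [DiscretizedHMM-class]), `logLik`
#'   (numeric trace, one entry per iteration), `iterations`, `converged`.
#' @export
baumWelch <- function(hmm, symbols, tol = 1e-6, maxIter = 500,
                      floorProb = 1e-6) {
  stopifnot(is(hmm, "DiscretizedHMM"))
  symbols <- .checkSymbols(symbols, ncol(hmm@B))
  if (length(symbols) < 2L) stop("need at least 2 symbols for Baum-Welch")
  s0 <- symbols - 1L
  M <- ncol(hmm@B)
  p <- hmm@pi; A <- hmm@A; B <- hmm@B
  trace <- numeric(0)
  converged <- FALSE
  symFactor <- factor(symbols, levels = 1:M)

  for (it in seq_len(maxIter)) {
    es <- .estep_cpp(p, A, B, s0)
    trace <- c(trace, es$logLik)
    if (it > 1L) {
      prev <- trace[it - 1L]
      if ((es$logLik - prev) < tol * abs(prev)) {
        converged <- TRUE
        break
      }
    }
    gamma <- es$gamma
    Anew <- es$xiSum / rowSums(es$xiSum)
    Bnew <- matrix(0, 3, M)
    grp <- rowsum(gamma, symFactor)   # rows: symbols present in the data
    Bnew[, as.integer(rownames(grp))] <- t(grp)
    Bnew <- Bnew / colSums(gamma)   # length-3 recycling divides row-wise
    pnew <- gamma[1, ]

    p <- floorVec(pnew, floorProb)
    A <- floorRows(Anew, floorProb)
    dimnames(A) <- list(.STATES, .STATES)
    B <- floorRows(Bnew, floorProb)
  }
  list(model = hmmModel(p, A, B, codebook = hmm@codebook),
       logLik = trace, iterations = length(trace), converged = converged)
}

#' Viterbi decoding of the most probable state path
#'
#' Dynamic-programming search (in log space, with backtracking) for the
#' single most probable vigilance-state sequence given the model and the
#' observed symbol sequence. Ties are broken toward the state earliest in
#' the WAKE, NREM, REM order.
#'
#' @param hmm a [DiscretizedHMM-class].
#' @param symbols integer symbols in `1..M`.
#' @param epochS epoch duration for the returned hypnogram (default 4 s).
#' @return list with `hypnogram` (a [Hypnogram-class]) and `logProb`, the
#'   decoded path's `log pi + sum log A + sum log B`.
#' @export
viterbiDecode <- function(hmm, symbols, epochS = 4) {
  stopifnot(is(hmm, "DiscretizedHMM"))
  symbols <- .checkSymbols(symbols, ncol(hmm@B))
  vt <- .viterbi_cpp(hmm@pi, hmm@A, hmm@B, symbols - 1L)
  list(hypnogram = hypnogram(.STATES[vt$path + 1L], epochS = epochS),
       logProb = vt$logProb)
}

#' Sample a state path and symbol sequence from an HMM
#'
#' Draws `T` states from the chain (`pi` then `A`) and one symbol per state
#' from `B`. Deterministic for a given seed.
#'
#' @param hmm a [DiscretizedHMM-class].
#' @param T sequence length (epochs).
#' @param seed integer RNG seed.
#' @param epochS epoch duration for the returned hypnogram (default 4 s).
#' @return list with `hypnogram` (a [Hypnogram-class]) and `symbols`
#'   (integer vector in `1..M`).
#' @export
sampleHMM <- function(hmm, T, seed = 0, epochS = 4) {
  stopifnot(is(hmm, "DiscretizedHMM"), T >= 1)
  T <- as.integer(T)
  M <- ncol(hmm@B)
  withSeed(seed, {
    states <- integer(T)
    states[1] <- sample.int(3L, 1L, prob = hmm@pi)
    if (T > 1L) for (t in 2:T)
      states[t] <- sample.int(3L, 1L, prob = hmm@A[states[t - 1L], ])
    u <- stats::runif(T)
    Bcum <- t(apply(hmm@B, 1, cumsum))
    symbols <- integer(T)
    for (t in seq_len(T))
      symbols[t] <- findInterval(u[t], Bcum[states[t], ],
                                 rightmost.closed = TRUE) + 1L
    list(hypnogram = hypnogram(.STATES[states], epochS = epochS),
         symbols = pmin(symbols, M))
  })
}
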