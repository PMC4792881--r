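#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. symbols are 0-based here (converted in R).
// Returns log-likelihood, scaled alpha (T x N) and scale factors.
// [[Rcpp::export(name = ".forward_cpp")]]
List forward_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                 IntegerVector symbols) {
  const int N = A.nrow();
  const int T = symbols.size();
  NumericMatrix alpha(T, N);
  NumericVector scale(T);

  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    alpha(0, i) = pi[i] * B(i, symbols[0]);
    s += alpha(0, i);
  }
  if (s <= 0.0) stop("all state paths impossible at t = 1");
  scale[0] = s;
  for (int i = 0; i < N; ++i) alpha(0, i) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double a = 0.0;
      for (int i = 0; i < N; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(j, symbols[t]);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("all state paths impossible at t = %d", t + 1);
    scale[t] = s;
    for (int j = 0; j < N; ++j) alpha(t, j) /= s;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]);
  return List::create(_["logLik"] = ll, _["alpha"] = alpha,
                      _["scale"] = scale);
}

// Scaled backward pass using the forward scale factors.
// [[Rcpp::export(name = ".backward_cpp")]]
NumericMatrix backward_cpp(NumericMatrix A, NumericMatrix B,
                           IntegerVector symbols, NumericVector scale) {
  const int N = A.nrow();
  const int T = symbols.size();
  NumericMatrix beta(T, N);
  for (int i = 0; i < N; ++i) beta(T - 1, i) = 1.0 / scale[T - 1];
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < N; ++i) {
      double b = 0.0;
      for (int j = 0; j < N; ++j)
        b += A(i, j) * B(j, symbols[t + 1]) * beta(t + 1, j);
      beta(t, i) = b / scale[t];
    }
  }
  return beta;
}

// Baum-Welch E-step: log-likelihood, state posteriors gamma (T x N) and
// expected transition counts xiSum (N x N).
// [[Rcpp::export(name = ".estep_cpp")]]
List estep_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
               IntegerVector symbols) {
  const int N = A.nrow();
  const int T = symbols.size();
  List fw = forward_cpp(pi, A, B, symbols);
  NumericMatrix alpha = fw["alpha"];
  NumericVector scale = fw["scale"];
  double ll = fw["logLik"];
  NumericMatrix beta = backward_cpp(A, B, symbols, scale);

  NumericMatrix gamma(T, N);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) {
      gamma(t, i) = alpha(t, i) * beta(t, i) * scale[t];
      s += gamma(t, i);
    }
    for (int i = 0; i < N; ++i) gamma(t, i) /= s;
  }

  NumericMatrix xiSum(N, N);
  for (int t = 0; t < T - 1; ++t) {
    double s = 0.0;
    std::vector<double> xi(N * N);
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) {
        double v = alpha(t, i) * A(i, j) * B(j, symbols[t + 1]) *
                   beta(t + 1, j);
        xi[i * N + j] = v;
        s += v;
      }
    if (s > 0.0)
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < N; ++j) xiSum(i, j) += xi[i * N + j] / s;
  }

  return List::create(_["logLik"] = ll, _["gamma"] = gamma,
                      _["xiSum"] = xiSum);
}

// Viterbi decoding in log space; ties broken toward the lowest state index.
// [[Rcpp::export(name = ".viterbi_cpp")]]
List viterbi_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                 IntegerVector symbols) {
  const int N = A.nrow();
  const int T = symbols.size();
  const double NEG_INF = -std::numeric_limits<double>::infinity();
  NumericMatrix delta(T, N);
  IntegerMatrix psi(T, N);

  for (int i = 0; i < N; ++i)
    delta(0, i) = std::log(pi[i]) + std::log(B(i, symbols[0]));

  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < N; ++j) {
      double best = NEG_INF;
      int arg = 0;
      for (int i = 0; i < N; ++i) {
        double v = delta(t - 1, i) + std::log(A(i, j));
        if (v > best) { best = v; arg = i; }  // strict > keeps lowest index
      }
      delta(t, j) = best + std::log(B(j, symbols[t]));
      psi(t, j) = arg;
    }
  }

  double best = NEG_INF;
  int arg = 0;
  for (int i = 0; i < N; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); arg = i; }
  if (best == NEG_INF) stop("all state paths impossible");

  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["logProb"] = best);
}
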