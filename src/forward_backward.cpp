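#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a (possibly subnormalised) HMM.
//
// logobs: T x K per-time log observation weights (for VBEM these are the
//   expected log emission densities; rows need not normalise).
// logpi:  length-K log initial weights.
// logA:   K x K log transition weights (rows need not normalise, as with
//   exp(E[log A]) under a Dirichlet posterior).
//
// Returns smoothed marginals gamma (T x K, rows sum to 1), the sum over t of
// the pairwise marginals xi (K x K), and logZ = log sum over all state paths
// of the weight products (the exact log normaliser).
// [[Rcpp::export]]
List fb_logspace(NumericMatrix logobs, NumericVector logpi, NumericMatrix logA) {
  const int T = logobs.nrow();
  const int K = logobs.ncol();

  NumericMatrix b(T, K);        // scaled obs weights exp(logobs - rowmax)
  NumericVector m(T);           // per-row max, re-added to logZ at the end
  for (int t = 0; t < T; ++t) {
    double mx = logobs(t, 0);
    for (int k = 1; k < K; ++k) if (logobs(t, k) > mx) mx = logobs(t, k);
    m[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logobs(t, k) - mx);
  }

  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));
  NumericVector pi(K);
  for (int k = 0; k < K; ++k) pi[k] = std::exp(logpi[k]);

  NumericMatrix alpha(T, K);
  NumericVector c(T);
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * b(0, k); s += alpha(0, k); }
  if (s <= 0.0) stop("forward pass underflow at t = 1");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;

  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= b(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (s <= 0.0) stop("forward pass underflow at t = %d", t + 1);
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  NumericMatrix beta(T, K), gamma(T, K), xi(K, K);
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double v = 0.0;
      for (int j = 0; j < K; ++j) v += A(i, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = v / c[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;  // guard tiny drift
  }
  for (int t = 0; t < T - 1; ++t) {
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * A(i, j) * b(t + 1, j) * beta(t + 1, j) / c[t + 1];
  }

  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(c[t]) + m[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logZ"] = logZ);
}
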