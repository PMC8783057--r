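#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward in the scaled (normalised) domain.
// logB: T x K expected log emission densities; logA: K x K expected log
// transition matrix; logpi: length-K expected log initial probabilities.
// Returns gamma (T x K posterior state probabilities), xi_sum (K x K summed
// pairwise posteriors) and loglik (log normaliser of the exponentiated
// expected-log parameters; for VB this is the data term of the ELBO).
// [[Rcpp::export]]
List fb_hmm(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  std::vector<double> c(T);
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));

  // emissions exponentiated with per-row max subtracted for stability
  NumericMatrix B(T, K);
  std::vector<double> bmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
    bmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  double ll = 0.0;
  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = std::exp(logpi[k]) * B(0, k);
    s += alpha(0, k);
  }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      a *= B(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + bmax[t];

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j)
        b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      s2 += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s2;
  }

  for (int t = 0; t < T - 1; ++t)
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) *
                    beta(t + 1, k) / c[t + 1];

  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = ll);
}

// Viterbi most-probable path (0-based state indices).
// [[Rcpp::export]]
IntegerVector viterbi_hmm(NumericMatrix logB, NumericMatrix logA,
                          NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = d(t - 1, 0) + logA(0, k);
      int arg = 0;
      for (int j = 1; j < K; ++j) {
        double v = d(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      d(t, k) = best + logB(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  for (int k = 1; k < K; ++k) if (d(T - 1, k) > d(T - 1, arg)) arg = k;
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}
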