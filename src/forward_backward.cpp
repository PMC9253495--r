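#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for an HMM with time-varying transition matrices.
//
// logdens: T x K log emission densities (rows of zeros for missing bins,
//          i.e. likelihood 1 for every state).
// pi0:     initial state distribution (length K).
// trans:   (T-1)*K*K vector, column-major array [j, k, t]:
//          trans[(t*K + k)*K + j] = P(S_{t+1}=k+1 | S_t=j+1).
//
// Returns posterior state probabilities gamma (T x K), expected transition
// probabilities xi ((T-1) x K*K, column (k*K + j) holds P(S_t=j+1,
// S_{t+1}=k+1 | O)), and the log-likelihood.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logdens, NumericVector pi0, NumericVector trans) {
  const int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix b(T, K), alpha(T, K), beta(T, K), gamma(T, K);
  NumericMatrix xi(T - 1, K * K);
  NumericVector c(T), rowmax(T);

  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logdens(t, k));
    rowmax[t] = m;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logdens(t, k) - m);
  }

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * b(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    const double *P = &trans[(size_t)(t - 1) * K * K];
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * P[k * K + j];
      a *= b(t, k);
      alpha(t, k) = a;
      s += a;
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double *P = &trans[(size_t)t * K * K];
    for (int j = 0; j < K; ++j) {
      double v = 0.0;
      for (int k = 0; k < K; ++k)
        v += P[k * K + j] * b(t + 1, k) * beta(t + 1, k);
      beta(t, j) = v / c[t + 1];
    }
  }

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    const double *P = &trans[(size_t)t * K * K];
    double tot = 0.0;
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < K; ++j) {
        double v = alpha(t, j) * P[k * K + j] * b(t + 1, k) * beta(t + 1, k) / c[t + 1];
        xi(t, k * K + j) = v;
        tot += v;
      }
    for (int q = 0; q < K * K; ++q) xi(t, q) /= tot;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(c[t]) + rowmax[t];
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}
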