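// Gaussian-emission hidden Markov model: Baum-Welch over multiple
// observation sequences (scaled forward-backward) and Viterbi decoding.
// Compiled because EM over pooled smFRET datasets (tens of thousands of
// bins, several candidate state counts, multiple restarts) is the hot loop
// of the analysis.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double gauss_pdf(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// [[Rcpp::export]]
List hmm_em(List seqs, NumericVector mu0, NumericVector sd0,
            NumericMatrix A0, NumericVector pi0, int max_iter,
            double tol) {
  const int K = mu0.size();
  const int S = seqs.size();
  std::vector<NumericVector> obs(S);
  for (int s = 0; s < S; ++s) obs[s] = as<NumericVector>(seqs[s]);

  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> pi(pi0.begin(), pi0.end());
  std::vector<double> A(K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) A[i * K + j] = A0(i, j);

  const double sd_floor = 1e-4;
  double loglik = -std::numeric_limits<double>::infinity();
  double prev_ll = loglik;
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < max_iter; ++iter) {
    // accumulators
    std::vector<double> pi_acc(K, 0.0), A_acc(K * K, 0.0);
    std::vector<double> w_acc(K, 0.0), wx_acc(K, 0.0), wxx_acc(K, 0.0);
    loglik = 0.0;

    for (int s = 0; s < S; ++s) {
      const NumericVector &x = obs[s];
      const int T = x.size();
      if (T == 0) continue;
      std::vector<double> B(T * K), alpha(T * K), beta(T * K), c(T);
      for (int t = 0; t < T; ++t)
        for (int k = 0; k < K; ++k) {
          double b = gauss_pdf(x[t], mu[k], sd[k]);
          B[t * K + k] = (b > 1e-300) ? b : 1e-300;
        }
      // forward, scaled
      double csum = 0.0;
      for (int k = 0; k < K; ++k) {
        alpha[k] = pi[k] * B[k];
        csum += alpha[k];
      }
      c[0] = csum;
      for (int k = 0; k < K; ++k) alpha[k] /= csum;
      for (int t = 1; t < T; ++t) {
        csum = 0.0;
        for (int j = 0; j < K; ++j) {
          double a = 0.0;
          for (int i = 0; i < K; ++i)
            a += alpha[(t - 1) * K + i] * A[i * K + j];
          a *= B[t * K + j];
          alpha[t * K + j] = a;
          csum += a;
        }
        c[t] = (csum > 0) ? csum : 1e-300;
        for (int j = 0; j < K; ++j) alpha[t * K + j] /= c[t];
      }
      // backward, scaled
      for (int k = 0; k < K; ++k) beta[(T - 1) * K + k] = 1.0;
      for (int t = T - 2; t >= 0; --t)
        for (int i = 0; i < K; ++i) {
          double b = 0.0;
          for (int j = 0; j < K; ++j)
            b += A[i * K + j] * B[(t + 1) * K + j] * beta[(t + 1) * K + j];
          beta[t * K + i] = b / c[t + 1];
        }
      for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

      // state posteriors and expected transitions
      for (int t = 0; t < T; ++t) {
        double g = 0.0;
        for (int k = 0; k < K; ++k) g += alpha[t * K + k] * beta[t * K + k];
        if (g <= 0) g = 1e-300;
        for (int k = 0; k < K; ++k) {
          double gamma = alpha[t * K + k] * beta[t * K + k] / g;
          if (t == 0) pi_acc[k] += gamma;
          w_acc[k] += gamma;
          wx_acc[k] += gamma * x[t];
          wxx_acc[k] += gamma * x[t] * x[t];
        }
      }
      for (int t = 0; t + 1 < T; ++t)
        for (int i = 0; i < K; ++i)
          for (int j = 0; j < K; ++j)
            A_acc[i * K + j] += alpha[t * K + i] * A[i * K + j] *
              B[(t + 1) * K + j] * beta[(t + 1) * K + j] / c[t + 1];
    }

    // M step
    double pisum = 0.0;
    for (int k = 0; k < K; ++k) pisum += pi_acc[k];
    for (int k = 0; k < K; ++k) pi[k] = (pisum > 0) ? pi_acc[k] / pisum : 1.0 / K;
    for (int i = 0; i < K; ++i) {
      double rs = 0.0;
      for (int j = 0; j < K; ++j) rs += A_acc[i * K + j];
      for (int j = 0; j < K; ++j)
        A[i * K + j] = (rs > 0) ? A_acc[i * K + j] / rs
                                : (i == j ? 1.0 : 0.0);
    }
    for (int k = 0; k < K; ++k) {
      if (w_acc[k] > 0) {
        mu[k] = wx_acc[k] / w_acc[k];
        double v = wxx_acc[k] / w_acc[k] - mu[k] * mu[k];
        sd[k] = std::sqrt(v > sd_floor * sd_floor ? v : sd_floor * sd_floor);
      }
    }

    if (iter > 0 && std::fabs(loglik - prev_ll) <
        tol * (1.0 + std::fabs(prev_ll))) {
      converged = true;
      break;
    }
    prev_ll = loglik;
  }

  NumericMatrix Aout(K, K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j) Aout(i, j) = A[i * K + j];
  return List::create(
    _["loglik"] = loglik,
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["sd"] = NumericVector(sd.begin(), sd.end()),
    _["A"] = Aout,
    _["pi"] = NumericVector(pi.begin(), pi.end()),
    _["iter"] = iter + 1,
    _["converged"] = converged);
}

// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericVector x, NumericVector mu,
                          NumericVector sd, NumericMatrix A,
                          NumericVector pi) {
  const int T = x.size(), K = mu.size();
  IntegerVector path(T);
  if (T == 0) return path;
  std::vector<double> delta(T * K);
  std::vector<int> psi(T * K, 0);
  const double neg_inf = -std::numeric_limits<double>::infinity();
  std::vector<double> logA(K * K);
  for (int i = 0; i < K; ++i)
    for (int j = 0; j < K; ++j)
      logA[i * K + j] = A(i, j) > 0 ? std::log(A(i, j)) : neg_inf;
  for (int k = 0; k < K; ++k)
    delta[k] = (pi[k] > 0 ? std::log(pi[k]) : neg_inf) +
      std::log(gauss_pdf(x[0], mu[k], sd[k]) + 1e-300);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < K; ++j) {
      double best = neg_inf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta[(t - 1) * K + i] + logA[i * K + j];
        if (v > best) { best = v; arg = i; }
      }
      delta[t * K + j] = best +
        std::log(gauss_pdf(x[t], mu[j], sd[j]) + 1e-300);
      psi[t * K + j] = arg;
    }
  int arg = 0;
  double best = neg_inf;
  for (int k = 0; k < K; ++k)
    if (delta[(T - 1) * K + k] > best) { best = delta[(T - 1) * K + k]; arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(t + 1) * K + path[t + 1]];
  return path;  // 0-based
}
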