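// EM inner loop for the ratio-estimate mixture model.
//
// Components: K Normal(mu_k, sigma_j^2) clusters, a Normal(0, sigma_j^2)
// null, and a Uniform(junk_lo, junk_hi) junk component. Per-variant
// variances are known; cluster means update as responsibility- and
// precision-weighted means, proportions as mean responsibilities.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
List em_fit_cpp(NumericVector theta, NumericVector sigma,
                NumericVector means_init, double junk_lo, double junk_hi,
                double overdispersion, double tol, int max_iter) {
  const int n = theta.size();
  const int K = means_init.size();
  const int C = K + 2;  // clusters, null, junk
  std::vector<double> means(means_init.begin(), means_init.end());
  std::vector<double> pi(C, 1.0 / C);
  std::vector<double> prec(n), log_const(n), logd_null(n);
  const double log2pi = std::log(2.0 * M_PI);
  for (int j = 0; j < n; ++j) {
    double s2 = sigma[j] * sigma[j] * overdispersion;
    prec[j] = 1.0 / s2;
    log_const[j] = -0.5 * (std::log(s2) + log2pi);
    logd_null[j] = log_const[j] - 0.5 * theta[j] * theta[j] * prec[j];
  }
  const double logd_junk_in = -std::log(junk_hi - junk_lo);
  std::vector<double> logd_junk(n);
  for (int j = 0; j < n; ++j)
    logd_junk[j] = (theta[j] >= junk_lo && theta[j] <= junk_hi)
                       ? logd_junk_in : R_NegInf;

  std::vector<double> trace;
  trace.reserve(256);
  std::vector<double> logw(C), resp_sum(C), mu_num(K), mu_den(K);
  NumericMatrix resp(n, C);
  double ll_prev = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    std::vector<double> logpi(C);
    for (int c = 0; c < C; ++c)
      logpi[c] = pi[c] > 0 ? std::log(pi[c]) : R_NegInf;
    double ll = 0.0;
    std::fill(resp_sum.begin(), resp_sum.end(), 0.0);
    std::fill(mu_num.begin(), mu_num.end(), 0.0);
    std::fill(mu_den.begin(), mu_den.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = theta[j] - means[k];
        logw[k] = logpi[k] + log_const[j] - 0.5 * d * d * prec[j];
        if (logw[k] > mx) mx = logw[k];
      }
      logw[K] = logpi[K] + logd_null[j];
      if (logw[K] > mx) mx = logw[K];
      logw[K + 1] = logpi[K + 1] + logd_junk[j];
      if (logw[K + 1] > mx) mx = logw[K + 1];
      double sum = 0.0;
      for (int c = 0; c < C; ++c) sum += std::exp(logw[c] - mx);
      double lse = mx + std::log(sum);
      ll += lse;
      for (int c = 0; c < C; ++c) {
        double r = std::exp(logw[c] - lse);
        resp(j, c) = r;
        resp_sum[c] += r;
        if (c < K) {
          mu_num[c] += r * prec[j] * theta[j];
          mu_den[c] += r * prec[j];
        }
      }
    }
    trace.push_back(ll);
    for (int k = 0; k < K; ++k)
      if (mu_den[k] > 0) means[k] = mu_num[k] / mu_den[k];
    for (int c = 0; c < C; ++c) pi[c] = resp_sum[c] / n;
    if (R_finite(ll_prev) && std::fabs(ll - ll_prev) < tol) break;
    ll_prev = ll;
  }
  return List::create(
      _["means"] = NumericVector(means.begin(), means.end()),
      _["pi"] = NumericVector(pi.begin(), pi.end()),
      _["trace"] = NumericVector(trace.begin(), trace.end()),
      _["log_likelihood"] = trace.back());
}
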