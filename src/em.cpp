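// Per-cell EM for the Gaussian mixture over segment LRC.
//
// Operates on per-segment sufficient statistics (L_k, sum x, sum x^2), which
// make every E/M quantity closed-form: the segment log-likelihood under
// state s is -L/2*log(2*pi*sigma^2) - (Sxx - 2*mu*Sx + L*mu^2)/(2*sigma^2)
// with mu_s = log2(0.5*c_s) + o for states c_s >= 1. State 0 (homozygous
// deletion) has the fixed mean mu0 = the LRC floor, which does not move with
// the baseline and therefore contributes neither to the o update nor to its
// normalizer. This is the fast path used by the fitting routine across the
// o grid; the reference R implementations of the E and M steps are tested
// against it.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using Rcpp::NumericVector;
using Rcpp::NumericMatrix;

// [[Rcpp::export(name = ".em_fit_cpp")]]
Rcpp::List em_fit_cpp(NumericVector L, NumericVector Sx, NumericVector Sxx,
                      NumericVector log_half_states, double mu0, double o0,
                      double sigma0, double tol, int max_iter,
                      double sigma_floor) {
  const int K = L.size(), S = log_half_states.size();
  const double LOG2PI = std::log(2.0 * M_PI);
  double o = o0, sigma = std::max(sigma0, sigma_floor);
  std::vector<double> pi(S, 1.0 / S);
  NumericMatrix gamma(K, S);
  std::vector<double> trace;
  double ll_prev = R_NegInf, ll = R_NegInf;
  int it = 0;
  bool converged = false;

  // state 0 is identified as the one whose log_half_states entry is NA or
  // by convention the first state when it equals 0 (handled by caller
  // passing log2(0.5*max(c,1)) and zero_first flag folded into mu0 use)
  std::vector<double> mu(S), logpi(S), lk(S);
  for (; it < max_iter; ++it) {
    const double s2 = sigma * sigma;
    for (int s = 0; s < S; ++s) {
      mu[s] = (s == 0) ? mu0 : log_half_states[s] + o;
      logpi[s] = std::log(std::max(pi[s], 1e-300));
    }
    // E-step in log space
    ll = 0.0;
    for (int k = 0; k < K; ++k) {
      double mx = R_NegInf;
      for (int s = 0; s < S; ++s) {
        double q = Sxx[k] - 2.0 * mu[s] * Sx[k] + L[k] * mu[s] * mu[s];
        lk[s] = logpi[s] - 0.5 * L[k] * (LOG2PI + std::log(s2)) -
                q / (2.0 * s2);
        if (lk[s] > mx) mx = lk[s];
      }
      double sum = 0.0;
      for (int s = 0; s < S; ++s) sum += std::exp(lk[s] - mx);
      double lse = mx + std::log(sum);
      ll += lse;
      for (int s = 0; s < S; ++s) gamma(k, s) = std::exp(lk[s] - lse);
    }
    trace.push_back(ll);
    if (it > 0 && std::fabs(ll - ll_prev) <
        tol * std::max(std::fabs(ll_prev), 1.0)) {
      converged = true;
      break;
    }
    ll_prev = ll;
    // M-step (closed form; o from the shifting states, then sigma at new o)
    double denom_o = 0.0, num_o = 0.0;
    for (int k = 0; k < K; ++k)
      for (int s = 1; s < S; ++s) {
        denom_o += gamma(k, s) * L[k];
        num_o += gamma(k, s) * (Sx[k] - L[k] * log_half_states[s]);
      }
    if (denom_o > 0) o = num_o / denom_o;
    double num_s = 0.0, denom_s = 0.0;
    for (int s = 0; s < S; ++s) mu[s] = (s == 0) ? mu0 : log_half_states[s] + o;
    for (int k = 0; k < K; ++k)
      for (int s = 0; s < S; ++s) {
        num_s += gamma(k, s) *
                 (Sxx[k] - 2.0 * mu[s] * Sx[k] + L[k] * mu[s] * mu[s]);
        denom_s += gamma(k, s) * L[k];
      }
    sigma = std::sqrt(std::max(num_s, 0.0) / denom_s);
    if (sigma < sigma_floor) sigma = sigma_floor;
    for (int s = 0; s < S; ++s) {
      double c = 0.0;
      for (int k = 0; k < K; ++k) c += gamma(k, s);
      pi[s] = c / K;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("o") = o, Rcpp::Named("sigma") = sigma,
      Rcpp::Named("pi") = NumericVector(pi.begin(), pi.end()),
      Rcpp::Named("gamma") = gamma, Rcpp::Named("loglik") = ll,
      Rcpp::Named("loglik_trace") = NumericVector(trace.begin(), trace.end()),
      Rcpp::Named("n_iter") = it + 1, Rcpp::Named("converged") = converged);
}
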