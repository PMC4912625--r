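#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zero-truncated Poisson-mixture fit by EM, alternated with a
// Horvitz-Thompson update of the unobserved zero class.
//
// The observed spectrum (sizes >= 1, clone counts) is augmented with a
// size-0 class whose count is the current missing-clone estimate
// D - n_obs, D = n_obs / (1 - P(0)). With the zero class held fixed, a
// standard Poisson-mixture EM is run to convergence; the zero class is
// then refreshed from the new fit, and the two steps alternate until the
// missing-clone count is self-consistent. The fixed point of this
// alternation is the conditional (zero-truncated) maximum-likelihood
// estimate.
//
// [[Rcpp::export]]
List em_truncated_mixture(NumericVector sizes, NumericVector counts,
                          NumericVector w0, NumericVector m0,
                          double tol, int max_iter, int max_alt,
                          double m_floor) {
  const int k = w0.size();
  const int S = sizes.size();
  const int n = S + 1;
  double n_obs = 0.0;
  for (int i = 0; i < S; ++i) n_obs += counts[i];

  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> m(m0.begin(), m0.end());
  for (int j = 0; j < k; ++j) if (m[j] < m_floor) m[j] = m_floor;

  std::vector<double> sz(n), c(n), lgam(n);
  sz[0] = 0.0; c[0] = 0.0;
  for (int i = 0; i < S; ++i) { sz[i + 1] = sizes[i]; c[i + 1] = counts[i]; }
  for (int i = 0; i < n; ++i) lgam[i] = std::lgamma(sz[i] + 1.0);

  double D = n_obs;
  bool converged = false;
  int alt = 0, em_iters = 0;
  for (alt = 0; alt < max_alt; ++alt) {
    double P0 = 0.0;
    for (int j = 0; j < k; ++j) P0 += w[j] * std::exp(-m[j]);
    if (P0 >= 1.0 - 1e-12)
      return List::create(_["ok"] = false,
                          _["reason"] = "no detection probability");
    double Dnew = n_obs / (1.0 - P0);
    bool self_consistent = (alt > 0 && std::fabs(Dnew - D) <= 1e-6 * Dnew);
    D = Dnew;
    c[0] = D - n_obs;
    if (self_consistent) { converged = true; break; }

    // EM over classes 0..T with the zero class held fixed
    double prev = R_NegInf;
    for (int it = 0; it < max_iter; ++it) {
      std::vector<double> sw(k, 0.0), sx(k, 0.0);
      double ll = 0.0;
      for (int i = 0; i < n; ++i) {
        if (c[i] <= 0.0 && i > 0) continue;
        double denom = 0.0;
        double f[64];
        for (int j = 0; j < k; ++j) {
          f[j] = w[j] * std::exp(-m[j] + sz[i] * std::log(m[j]) - lgam[i]);
          denom += f[j];
        }
        if (denom < 1e-300) denom = 1e-300;
        ll += c[i] * std::log(denom);
        const double ci = c[i] / denom;
        for (int j = 0; j < k; ++j) {
          const double r = ci * f[j];
          sw[j] += r;
          sx[j] += r * sz[i];
        }
      }
      double tot = 0.0;
      for (int j = 0; j < k; ++j) tot += sw[j];
      double wsum = 0.0;
      for (int j = 0; j < k; ++j) {
        w[j] = sw[j] / tot;
        if (w[j] < 1e-12) w[j] = 1e-12;
        wsum += w[j];
        m[j] = (sw[j] > 1e-300) ? sx[j] / sw[j] : m_floor;
        if (m[j] < m_floor) m[j] = m_floor;
      }
      for (int j = 0; j < k; ++j) w[j] /= wsum;
      ++em_iters;
      if (it > 0 && std::fabs(ll - prev) <= tol * (std::fabs(ll) + 1.0)) break;
      prev = ll;
    }
  }

  double P0 = 0.0;
  for (int j = 0; j < k; ++j) P0 += w[j] * std::exp(-m[j]);
  if (P0 >= 1.0 - 1e-12)
    return List::create(_["ok"] = false,
                        _["reason"] = "no detection probability");
  D = n_obs / (1.0 - P0);

  // conditional (zero-truncated) log-likelihood of the observed spectrum
  double ll_cond = 0.0;
  const double log1mP0 = std::log1p(-P0);
  for (int i = 1; i < n; ++i) {
    double Pi = 0.0;
    for (int j = 0; j < k; ++j)
      Pi += w[j] * std::exp(-m[j] + sz[i] * std::log(m[j]) - lgam[i]);
    if (Pi <= 0.0) { ll_cond = R_NegInf; break; }
    ll_cond += c[i] * (std::log(Pi) - log1mP0);
  }

  return List::create(_["ok"] = true,
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["m"] = NumericVector(m.begin(), m.end()),
                      _["D_total"] = D,
                      _["missing"] = D - n_obs,
                      _["loglik"] = ll_cond,
                      _["converged"] = converged,
                      _["alternations"] = alt,
                      _["em_iterations"] = em_iters);
}
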