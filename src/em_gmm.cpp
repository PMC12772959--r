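#include <Rcpp.h>
using namespace Rcpp;

// One EM run for a 1-D Gaussian mixture from given initial parameters.
// Returns loglik = -Inf if a component dies (degenerate run).
// [[Rcpp::export(name = ".em_gmm1d_run")]]
List em_gmm1d_run(NumericVector x, NumericVector mu0, NumericVector v0,
                  NumericVector w0, double tol, int max_iter,
                  double var_floor) {
  const int n = x.size(), k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> lp(k), nk(k), sx(k), sxx(k);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false;
  const double l2pi = std::log(2.0 * M_PI);

  for (int it = 0; it < max_iter; ++it) {
    std::vector<double> logw(k), halflogv(k), inv2v(k);
    for (int j = 0; j < k; ++j) {
      logw[j] = std::log(w[j]);
      halflogv[j] = 0.5 * (l2pi + std::log(v[j]));
      inv2v[j] = 0.5 / v[j];
      nk[j] = sx[j] = sxx[j] = 0.0;
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int j = 0; j < k; ++j) {
        double d = x[i] - mu[j];
        lp[j] = logw[j] - halflogv[j] - d * d * inv2v[j];
        if (lp[j] > m) m = lp[j];
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(lp[j] - m);
      double lse = m + std::log(s);
      ll += lse;
      for (int j = 0; j < k; ++j) {
        double g = std::exp(lp[j] - lse);
        nk[j] += g;
        sx[j] += g * x[i];
        sxx[j] += g * x[i] * x[i];
      }
    }
    bool dead = false;
    for (int j = 0; j < k; ++j) if (nk[j] < 1e-8) dead = true;
    if (dead) { ll = R_NegInf; break; }
    for (int j = 0; j < k; ++j) {
      w[j] = nk[j] / n;
      mu[j] = sx[j] / nk[j];
      double vj = sxx[j] / nk[j] - mu[j] * mu[j];
      v[j] = vj > var_floor ? vj : var_floor;
    }
    if (R_finite(ll_old) && ll - ll_old < tol * (1.0 + std::fabs(ll))) {
      converged = true;
      break;
    }
    ll_old = ll;
  }
  return List::create(_["mean"] = NumericVector(mu.begin(), mu.end()),
                      _["var"] = NumericVector(v.begin(), v.end()),
                      _["weight"] = NumericVector(w.begin(), w.end()),
                      _["loglik"] = ll, _["converged"] = converged);
}
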