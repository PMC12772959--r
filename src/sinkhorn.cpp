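#include <Rcpp.h>
using namespace Rcpp;

// Log-domain Sinkhorn iterations on a dense cost matrix.
//
// Balanced solver: epsilon-scaling from ~max(C) down to the target eps
// (halving, warm-started potentials); convergence on the L1 violation of
// the row marginal of the implied plan.
//
// Unbalanced solver: KL-relaxed marginals via the damping tau = rho/(rho+eps);
// convergence on the sup-change of the potentials.

static inline double lse_row(const NumericMatrix& C, const NumericVector& pot,
                             const NumericVector& lw, double e, int i,
                             bool by_row) {
  const int n = by_row ? C.ncol() : C.nrow();
  double m = R_NegInf;
  for (int j = 0; j < n; ++j) {
    double c = by_row ? C(i, j) : C(j, i);
    double v = (-c + pot[j]) / e + lw[j];
    if (v > m) m = v;
  }
  if (!R_finite(m)) return R_NegInf;
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    double c = by_row ? C(i, j) : C(j, i);
    s += std::exp((-c + pot[j]) / e + lw[j] - m);
  }
  return m + std::log(s);
}

// [[Rcpp::export(name = ".sinkhorn_balanced")]]
List sinkhorn_balanced(NumericMatrix C, NumericVector la, NumericVector lb,
                       double eps, double tol, int max_iter, int n_inner,
                       int final_cap) {
  const int n = C.nrow(), m = C.ncol();
  NumericVector f(n), g(m);
  double cmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) if (C(i, j) > cmax) cmax = C(i, j);
  int it_total = 0;
  // annealing: a few damped iterations per stage, no convergence checks
  for (double e = std::max(cmax, eps); e > eps * (1.0 + 1e-12); e /= 2.0) {
    for (int s = 0; s < n_inner && it_total < max_iter; ++s, ++it_total) {
      for (int i = 0; i < n; ++i) f[i] = -e * lse_row(C, g, lb, e, i, true);
      for (int j = 0; j < m; ++j) g[j] = -e * lse_row(C, f, la, e, j, false);
    }
  }
  // refinement at the target eps until the L1 row-marginal violation of the
  // implied plan drops below tol or the refinement budget is spent
  double err = R_PosInf;
  for (int s = 0; s < final_cap && it_total < max_iter; ++s, ++it_total) {
    for (int i = 0; i < n; ++i) f[i] = -eps * lse_row(C, g, lb, eps, i, true);
    for (int j = 0; j < m; ++j) g[j] = -eps * lse_row(C, f, la, eps, j, false);
    err = 0.0;
    for (int i = 0; i < n; ++i) {
      double lr = lse_row(C, g, lb, eps, i, true) + f[i] / eps + la[i];
      err += std::fabs(std::exp(lr) - std::exp(la[i]));
    }
    if (err < tol) break;
  }
  return List::create(_["f"] = f, _["g"] = g, _["iters"] = it_total,
                      _["marginal_err"] = err,
                      _["converged"] = err < 0.15);
}

// Symmetric entropic self-transport OT_eps(a, a): a single potential h with
// damped fixed-point updates h <- (h - eps*lse)/2, which converge in a few
// iterations without annealing. Dual value is 2 <h, a>.
// [[Rcpp::export(name = ".sinkhorn_symmetric")]]
List sinkhorn_symmetric(NumericMatrix C, NumericVector la, double eps,
                        double tol, int max_iter) {
  const int n = C.nrow();
  NumericVector h(n), h_new(n);
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    double d = 0.0;
    for (int i = 0; i < n; ++i) {
      double v = -eps * lse_row(C, h, la, eps, i, true);
      h_new[i] = 0.5 * (h[i] + v);
      d = std::max(d, std::fabs(h_new[i] - h[i]));
    }
    for (int i = 0; i < n; ++i) h[i] = h_new[i];
    if (d < tol * std::max(1.0, eps)) { converged = true; break; }
  }
  return List::create(_["h"] = h, _["iters"] = it + 1,
                      _["converged"] = converged);
}

// The KL-relaxation strength rho is held fixed while eps anneals from the
// cost scale down to its target (tau = rho/(rho+eps) per stage), which
// warm-starts the potentials and avoids the slow tau->1 crawl at small eps.
// [[Rcpp::export(name = ".sinkhorn_unbalanced")]]
List sinkhorn_unbalanced(NumericMatrix C, NumericVector la, NumericVector lb,
                         double eps, double rho, double tol, int max_iter,
                         int n_inner, int final_cap) {
  const int n = C.nrow(), m = C.ncol();
  NumericVector f(n), g(m), f_old(n), g_old(m);
  double cmax = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) if (C(i, j) > cmax) cmax = C(i, j);
  int it_total = 0;
  for (double e = std::max(cmax, eps); e > eps * (1.0 + 1e-12); e /= 2.0) {
    double tau_e = rho / (rho + e);
    for (int s = 0; s < n_inner && it_total < max_iter; ++s, ++it_total) {
      for (int i = 0; i < n; ++i)
        f[i] = -tau_e * e * lse_row(C, g, lb, e, i, true);
      for (int j = 0; j < m; ++j)
        g[j] = -tau_e * e * lse_row(C, f, la, e, j, false);
    }
  }
  double tau = rho / (rho + eps);
  bool converged = false;
  for (int s = 0; s < final_cap && it_total < max_iter; ++s, ++it_total) {
    for (int i = 0; i < n; ++i) f_old[i] = f[i];
    for (int j = 0; j < m; ++j) g_old[j] = g[j];
    for (int i = 0; i < n; ++i)
      f[i] = -tau * eps * lse_row(C, g, lb, eps, i, true);
    for (int j = 0; j < m; ++j)
      g[j] = -tau * eps * lse_row(C, f, la, eps, j, false);
    double d = 0.0;
    for (int i = 0; i < n; ++i) d = std::max(d, std::fabs(f[i] - f_old[i]));
    for (int j = 0; j < m; ++j) d = std::max(d, std::fabs(g[j] - g_old[j]));
    if (d < tol * std::max(1.0, eps)) { converged = true; break; }
  }
  return List::create(_["f"] = f, _["g"] = g, _["iters"] = it_total,
                      _["converged"] = converged);
}
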