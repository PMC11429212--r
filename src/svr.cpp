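#include <Rcpp.h>
using namespace Rcpp;

// SMO solver for the epsilon-SVR dual with an RBF kernel.
// 2n-variable formulation: alpha_p, p < n are the a_i (sign +1), p >= n the
// a_i* (sign -1); minimize 1/2 a'Qa + p'a with Q_pq = z_p z_q K_ij,
// p_p = eps - z_p y_i, subject to sum z_p a_p = 0 and 0 <= a_p <= C.
// Maximal-violating-pair working set selection; the bias is the midpoint of
// the KKT bounds at convergence.
// [[Rcpp::export]]
List svr_smo(NumericMatrix K, NumericVector y, double C, double eps,
             double tol, int max_iter) {
  int n = y.size();
  int N = 2 * n;
  std::vector<double> a(N, 0.0), G(N);
  auto z = [&](int p) { return p < n ? 1.0 : -1.0; };
  auto ix = [&](int p) { return p < n ? p : p - n; };
  for (int p = 0; p < N; ++p) G[p] = eps - z(p) * y[ix(p)];

  int iter = 0;
  double m_up = 0, m_low = 0;
  for (; iter < max_iter; ++iter) {
    // working set: maximal violating pair
    int i = -1, j = -1;
    m_up = -std::numeric_limits<double>::infinity();
    m_low = std::numeric_limits<double>::infinity();
    for (int p = 0; p < N; ++p) {
      double zp = z(p);
      bool up = (zp > 0 && a[p] < C) || (zp < 0 && a[p] > 0);
      bool low = (zp > 0 && a[p] > 0) || (zp < 0 && a[p] < C);
      double v = -zp * G[p];
      if (up && v > m_up) { m_up = v; i = p; }
      if (low && v < m_low) { m_low = v; j = p; }
    }
    if (i < 0 || j < 0 || m_up - m_low <= tol) break;

    int ii = ix(i), jj = ix(j);
    double zi = z(i), zj = z(j);
    double eta = K(ii, ii) + K(jj, jj) - 2.0 * K(ii, jj);
    if (eta < 1e-12) eta = 1e-12;
    // direction: a_i += zi * t, a_j -= zj * t
    double t = (m_up - m_low) / eta;
    // box clipping
    double tmax = t;
    if (zi > 0) tmax = std::min(tmax, C - a[i]); else tmax = std::min(tmax, a[i]);
    if (zj > 0) tmax = std::min(tmax, a[j]); else tmax = std::min(tmax, C - a[j]);
    t = std::max(0.0, tmax);
    if (t <= 0) break;
    a[i] += zi > 0 ? t : -t;
    a[j] -= zj > 0 ? t : -t;
    for (int p = 0; p < N; ++p) {
      G[p] += z(p) * t * (K(ix(p), ii) - K(ix(p), jj));
    }
  }
  double b = (m_up + m_low) / 2.0;
  NumericVector beta(n);
  for (int q = 0; q < n; ++q) beta[q] = a[q] - a[q + n];
  return List::create(_["beta"] = beta, _["b"] = b, _["iterations"] = iter,
                      _["gap"] = m_up - m_low);
}
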