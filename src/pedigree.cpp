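#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo-style inbreeding: for each animal with both parents known,
// accumulate a_ii = sum_j L_j^2 d_j by pushing gene contributions from the
// animal down to its ancestors (parents precede offspring in the sorted
// pedigree, so ancestor indices are strictly smaller).
// [[Rcpp::export]]
List ml_inbreeding(IntegerVector si, IntegerVector di) {
  int n = si.size();
  NumericVector F(n), d(n);
  std::vector<double> L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = si[i] - 1, dd = di[i] - 1;  // -1 = unknown
    double Fs = (s >= 0) ? F[s] : -1.0;
    double Fd = (dd >= 0) ? F[dd] : -1.0;
    d[i] = 0.5 - 0.25 * (Fs + Fd);
    if (s < 0 || dd < 0) { F[i] = 0.0; continue; }
    // traverse ancestors of i (including i itself)
    double a = 0.0;
    L[i] = 1.0;
    for (int j = i; j >= 0; --j) {
      double lj = L[j];
      if (lj == 0.0) continue;
      a += lj * lj * d[j];
      int js = si[j] - 1, jd = di[j] - 1;
      if (js >= 0) L[js] += 0.5 * lj;
      if (jd >= 0) L[jd] += 0.5 * lj;
      L[j] = 0.0;
    }
    F[i] = a - 1.0;
  }
  return List::create(_["F"] = F, _["d"] = d);
}

// Takahashi selected inverse. Input: simplicial LDL' factor in CSC form
// (lower triangular, sorted row indices, diagonal entry first in each column
// holding D, off-diagonals holding unit-L entries), as produced by CHOLMOD.
// Output: values of Z = inv(L D L') on the same sparsity pattern.
//
// Recurrence (Erisman & Tinney), columns processed right to left, rows of a
// column from the bottom up:
//   Z[i,j] = delta_ij / d_j - sum_{k in struct(col j), k > j} L[k,j] * Z[*]
// where Z[*] = Z[max(i,k), min(i,k)], guaranteed to lie in the pattern by the
// elimination-tree path property.
// [[Rcpp::export]]
NumericVector takahashi_inverse(IntegerVector p, IntegerVector ri, NumericVector x) {
  int n = p.size() - 1;
  NumericVector z(x.size());
  std::vector<double> work(n, 0.0);  // scatter buffer for one Z column
  std::vector<double> accv;
  for (int j = n - 1; j >= 0; --j) {
    int start = p[j], end = p[j + 1];
    int m = end - start;  // diagonal + off-diagonals, rows ascending
    accv.assign(m, 0.0);
    // accumulate sum_k L[k,j] * Z(max(i,k), min(i,k)) for every target
    // i in struct(col j), decomposed by c = min(i,k); Z column c is
    // scattered once into the dense buffer.
    for (int tc = start + 1; tc < end; ++tc) {
      int c = ri[tc];
      double Lcj = x[tc];
      for (int t = p[c]; t < p[c + 1]; ++t) work[ri[t]] = z[t];
      // pairs with k = c <= i
      for (int t = tc; t < end; ++t) accv[t - start] += Lcj * work[ri[t]];
      // pairs with i = c < k
      double s = 0.0;
      for (int t = tc + 1; t < end; ++t) s += x[t] * work[ri[t]];
      accv[tc - start] += s;
      for (int t = p[c]; t < p[c + 1]; ++t) work[ri[t]] = 0.0;
    }
    for (int t = start + 1; t < end; ++t) z[t] = -accv[t - start];
    double acc = 0.0;
    for (int t = start + 1; t < end; ++t) acc += x[t] * z[t];
    z[start] = 1.0 / x[start] - acc;
  }
  return z;
}
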