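#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Regression forest: bagged trees grown by best-variance-reduction splits
// among m randomly drawn features, terminal nodes of at least one point,
// nodes of size <= n_min not split further. Per-tree RNG streams are seeded
// from R so results are reproducible and independent of tree order.

struct Tree {
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
};

static void grow(Tree &tr, const NumericMatrix &X, const NumericVector &y,
                 std::vector<int> &idx, int lo, int hi, int m, int n_min,
                 std::mt19937 &rng, int node) {
  int n = hi - lo;
  double sum = 0, sum2 = 0;
  for (int q = lo; q < hi; ++q) { sum += y[idx[q]]; sum2 += y[idx[q]] * y[idx[q]]; }
  double mean = sum / n;
  tr.value[node] = mean;
  if (n <= n_min || sum2 - sum * mean < 1e-12) return;

  int p = X.ncol();
  // draw m distinct features
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  for (int f = 0; f < m && f < p; ++f) {
    std::uniform_int_distribution<int> U(f, p - 1);
    std::swap(feats[f], feats[U(rng)]);
  }
  double best_gain = 0, best_thr = 0;
  int best_f = -1;
  std::vector<std::pair<double, double>> vals(n);
  for (int f = 0; f < m && f < p; ++f) {
    int fe = feats[f];
    for (int q = 0; q < n; ++q)
      vals[q] = {X(idx[lo + q], fe), y[idx[lo + q]]};
    std::sort(vals.begin(), vals.end());
    double ls = 0;
    for (int q = 0; q < n - 1; ++q) {
      ls += vals[q].second;
      if (vals[q + 1].first <= vals[q].first) continue;
      int nl = q + 1, nr = n - nl;
      double rs = sum - ls;
      double gain = ls * ls / nl + rs * rs / nr - sum * mean;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_f = fe;
        best_thr = 0.5 * (vals[q].first + vals[q + 1].first);
      }
    }
  }
  if (best_f < 0) return;
  // partition idx[lo, hi) by the split
  int mid = lo;
  for (int q = lo; q < hi; ++q) {
    if (X(idx[q], best_f) <= best_thr) std::swap(idx[q], idx[mid++]);
  }
  if (mid == lo || mid == hi) return;
  tr.feature[node] = best_f;
  tr.threshold[node] = best_thr;
  int lnode = tr.feature.size();
  tr.feature.push_back(-1); tr.threshold.push_back(0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);
  int rnode = tr.feature.size();
  tr.feature.push_back(-1); tr.threshold.push_back(0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.value.push_back(0);
  tr.left[node] = lnode;
  tr.right[node] = rnode;
  grow(tr, X, y, idx, lo, mid, m, n_min, rng, lnode);
  grow(tr, X, y, idx, mid, hi, m, n_min, rng, rnode);
}

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int k, int m, int n_min,
                IntegerVector tree_seeds) {
  int n = X.nrow();
  List forest(k);
  IntegerMatrix inbag(n, k);
  for (int b = 0; b < k; ++b) {
    std::mt19937 rng(static_cast<unsigned>(tree_seeds[b]));
    std::uniform_int_distribution<int> U(0, n - 1);
    std::vector<int> idx(n);
    for (int q = 0; q < n; ++q) {
      idx[q] = U(rng);
      inbag(idx[q], b)++;
    }
    Tree tr;
    tr.feature.assign(1, -1); tr.threshold.assign(1, 0.0);
    tr.left.assign(1, -1); tr.right.assign(1, -1); tr.value.assign(1, 0.0);
    grow(tr, X, y, idx, 0, n, m, n_min, rng, 0);
    forest[b] = List::create(_["feature"] = wrap(tr.feature),
                             _["threshold"] = wrap(tr.threshold),
                             _["left"] = wrap(tr.left),
                             _["right"] = wrap(tr.right),
                             _["value"] = wrap(tr.value));
  }
  return List::create(_["trees"] = forest, _["inbag"] = inbag);
}

// [[Rcpp::export]]
NumericMatrix rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), k = trees.size();
  NumericMatrix out(n, k);
  for (int b = 0; b < k; ++b) {
    List tr = trees[b];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"], value = tr["value"];
    for (int q = 0; q < n; ++q) {
      int node = 0;
      while (feature[node] >= 0) {
        node = X(q, feature[node]) <= threshold[node] ? left[node] : right[node];
      }
      out(q, b) = value[node];
    }
  }
  return out;
}
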