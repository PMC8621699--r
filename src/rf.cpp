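#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Minimal Breiman-style random forest for binary classification:
// bootstrap bagging, mtry features per split, exact Gini split search,
// leaves store the class-1 fraction. Self-contained xorshift RNG so the
// forest is bit-reproducible for a fixed seed regardless of R's RNG state.

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int unif_int(int n) { return (int)(next() % (uint64_t)n); }
};

struct Node {
  int feature = -1;      // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  double pred = 0.0;     // leaf class-1 fraction
};

struct SplitResult {
  int feature = -1;
  double thr = 0.0;
  double gain = 0.0;
};

double gini_impurity(double n1, double n) {
  if (n <= 0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

SplitResult best_split(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<int>& idx,
                       const std::vector<int>& feats) {
  SplitResult best;
  const int n = idx.size();
  double n1_tot = 0;
  for (int i : idx) n1_tot += y[i];
  const double imp_parent = gini_impurity(n1_tot, n);
  std::vector<std::pair<double, int>> vals(n);
  for (int f : feats) {
    for (int r = 0; r < n; ++r) vals[r] = {X(idx[r], f), y[idx[r]]};
    std::sort(vals.begin(), vals.end());
    if (vals.front().first == vals.back().first) continue;
    double nl = 0, n1l = 0;
    for (int r = 0; r < n - 1; ++r) {
      nl += 1.0; n1l += vals[r].second;
      if (vals[r].first == vals[r + 1].first) continue;
      double nr = n - nl, n1r = n1_tot - n1l;
      double imp = (nl / n) * gini_impurity(n1l, nl) +
                   (nr / n) * gini_impurity(n1r, nr);
      double gain = imp_parent - imp;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.thr = 0.5 * (vals[r].first + vals[r + 1].first);
      }
    }
  }
  return best;
}

int build_node(const NumericMatrix& X, const IntegerVector& y,
               std::vector<int>& idx, int depth, int max_depth, int min_node,
               int mtry, XorShift& rng, std::vector<Node>& nodes) {
  Node nd;
  const int n = idx.size();
  double n1 = 0;
  for (int i : idx) n1 += y[i];
  nd.pred = n1 / n;
  const int me = nodes.size();
  nodes.push_back(nd);
  if (depth >= max_depth || n < 2 * min_node || n1 == 0 || n1 == n)
    return me;

  // sample mtry distinct features (partial Fisher-Yates)
  const int p = X.ncol();
  std::vector<int> all(p);
  for (int f = 0; f < p; ++f) all[f] = f;
  const int m = std::min(mtry, p);
  for (int k = 0; k < m; ++k) std::swap(all[k], all[k + rng.unif_int(p - k)]);
  all.resize(m);

  SplitResult sp = best_split(X, y, idx, all);
  if (sp.feature < 0) return me;

  std::vector<int> li, ri;
  for (int i : idx) {
    if (X(i, sp.feature) <= sp.thr) li.push_back(i); else ri.push_back(i);
  }
  if ((int)li.size() < min_node || (int)ri.size() < min_node) return me;
  idx.clear(); idx.shrink_to_fit();
  int l = build_node(X, y, li, depth + 1, max_depth, min_node, mtry, rng, nodes);
  int r = build_node(X, y, ri, depth + 1, max_depth, min_node, mtry, rng, nodes);
  nodes[me].feature = sp.feature;
  nodes[me].thr = sp.thr;
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

List pack_tree(const std::vector<Node>& nodes) {
  const int n = nodes.size();
  IntegerVector feature(n), left(n), right(n);
  NumericVector thr(n), pred(n);
  for (int i = 0; i < n; ++i) {
    feature[i] = nodes[i].feature; thr[i] = nodes[i].thr;
    left[i] = nodes[i].left; right[i] = nodes[i].right; pred[i] = nodes[i].pred;
  }
  return List::create(_["feature"] = feature, _["thr"] = thr,
                      _["left"] = left, _["right"] = right, _["pred"] = pred);
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            int min_node, int max_depth, int seed) {
  const int n = X.nrow();
  List forest(ntree);
  for (int t = 0; t < ntree; ++t) {
    XorShift rng((uint64_t)seed * 1000003ULL + t + 1);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);  // bootstrap
    std::vector<Node> nodes;
    nodes.reserve(64);
    build_node(X, y, idx, 0, max_depth, min_node, mtry, rng, nodes);
    forest[t] = pack_tree(nodes);
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List forest, NumericMatrix X) {
  const int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0)
        nd = (X(i, feature[nd]) <= thr[nd]) ? left[nd] : right[nd];
      out[i] += pred[nd];
    }
  }
  return out / (double)T;
}
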