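// Compact classification random forest (binary labels, Gini splits).
// Trees are grown on bootstrap samples with a random feature subset per
// node; predictions are tree-vote fractions, giving a [0,1] score that the
// consensus layer can average.  Kept deliberately small: the package needs
// a dependable forest, not a framework.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;       // -1 => leaf
  double threshold = 0.0; // goes left if x <= threshold
  int left = -1, right = -1;
  double prob = 0.5;      // positive fraction at the node
};

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node, max_depth;
  Rng& rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int min_node_, int max_depth_, Rng& rng_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_),
        max_depth(max_depth_), rng(rng_) {}

  int build(std::vector<int>& idx, int depth) {
    int id = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    int n = static_cast<int>(idx.size());
    int pos = 0;
    for (int i : idx) pos += y[i];
    nodes[id].prob = n ? static_cast<double>(pos) / n : 0.5;
    if (n < 2 * min_node || depth >= max_depth || pos == 0 || pos == n)
      return id;

    // sample mtry features without replacement
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j)
      std::swap(feats[j], feats[j + rng.unif_int(p - j)]);

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double parent_imp = 1.0 - nodes[id].prob * nodes[id].prob -
                        (1.0 - nodes[id].prob) * (1.0 - nodes[id].prob);
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < mtry && jj < p; ++jj) {
      int f = feats[jj];
      for (int k = 0; k < n; ++k) vals[k] = {X(idx[k], f), y[idx[k]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      int lpos = 0;
      for (int k = 0; k < n - 1; ++k) {
        lpos += vals[k].second;
        if (vals[k].first == vals[k + 1].first) continue;
        int ln = k + 1, rn = n - ln;
        if (ln < min_node || rn < min_node) continue;
        double pl = static_cast<double>(lpos) / ln;
        double pr = static_cast<double>(pos - lpos) / rn;
        double impl = 2.0 * pl * (1.0 - pl);
        double impr = 2.0 * pr * (1.0 - pr);
        double gain = parent_imp -
            (ln * impl + rn * impr) / static_cast<double>(n);
        if (gain > best_gain) {
          best_gain = gain; best_f = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
    if (best_f < 0) return id;

    std::vector<int> lidx, ridx;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) lidx.push_back(i);
      else ridx.push_back(i);
    }
    if (lidx.empty() || ridx.empty()) return id;
    nodes[id].feature = best_f;
    nodes[id].threshold = best_thr;
    nodes[id].left = build(lidx, depth + 1);
    nodes[id].right = build(ridx, depth + 1);
    return id;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_forest_fit")]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                    int min_node, int max_depth, int seed) {
  int n = X.nrow();
  if (n == 0) stop("empty training matrix");
  Rng rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);  // bootstrap
    TreeBuilder tb(X, y, mtry, min_node, max_depth, rng);
    tb.build(idx, 0);
    int m = static_cast<int>(tb.nodes.size());
    NumericMatrix tm(m, 5);
    for (int k = 0; k < m; ++k) {
      tm(k, 0) = tb.nodes[k].feature;
      tm(k, 1) = tb.nodes[k].threshold;
      tm(k, 2) = tb.nodes[k].left;
      tm(k, 3) = tb.nodes[k].right;
      tm(k, 4) = tb.nodes[k].prob;
    }
    trees[t] = tm;
  }
  return trees;
}

// [[Rcpp::export(name = ".cpp_forest_predict")]]
NumericVector cpp_forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tm = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tm(node, 0) >= 0) {
        int f = static_cast<int>(tm(node, 0));
        node = (X(i, f) <= tm(node, 1)) ? static_cast<int>(tm(node, 2))
                                        : static_cast<int>(tm(node, 3));
      }
      out[i] += tm(node, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
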