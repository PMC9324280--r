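// Minimal random-forest classifier (CART trees, Gini impurity, bootstrap
// bags, mtry feature subsampling).  Scores are the forest-average leaf
// fraction of the positive class, giving a continuous output in [0, 1].
// Self-contained because no tree package ships with the target library.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct TreeNode {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // leaf: fraction of class 1
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int p, mtry, maxdepth, minsplit;
  std::mt19937& rng;
  std::vector<TreeNode> nodes;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
              int maxdepth_, int minsplit_, std::mt19937& rng_)
      : X(X_), y(y_), p(X_.ncol()), mtry(mtry_), maxdepth(maxdepth_),
        minsplit(minsplit_), rng(rng_) {}

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    int pos = 0;
    for (int i = 0; i < n; ++i) pos += y[idx[i]];
    int node_id = (int)nodes.size();
    nodes.push_back(TreeNode());
    TreeNode& self = nodes[node_id];
    self.feature = -1;
    self.value = (double)pos / n;
    self.left = self.right = -1;
    bool pure = (pos == 0 || pos == n);
    if (pure || n < minsplit || (maxdepth > 0 && depth >= maxdepth))
      return node_id;

    // Sample mtry candidate features without replacement.
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    for (int j = 0; j < mtry && j < p; ++j) {
      std::uniform_int_distribution<int> U(j, p - 1);
      std::swap(feats[j], feats[U(rng)]);
    }

    double best_gain = 0.0, best_thr = 0.0;
    int best_feat = -1;
    double parent_imp = 2.0 * self.value * (1.0 - self.value);
    std::vector<std::pair<double, int> > vals(n);
    for (int f = 0; f < mtry && f < p; ++f) {
      int j = feats[f];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], j), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      int lpos = 0;
      for (int i = 0; i < n - 1; ++i) {
        lpos += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double pl = (double)lpos / nl, pr = (double)(pos - lpos) / nr;
        double imp = ((double)nl / n) * 2.0 * pl * (1.0 - pl) +
                     ((double)nr / n) * 2.0 * pr * (1.0 - pr);
        double gain = parent_imp - imp;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_feat = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_feat < 0) return node_id;

    std::vector<int> lidx, ridx;
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], best_feat) <= best_thr) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    if (lidx.empty() || ridx.empty()) return node_id;
    int l = build(lidx, depth + 1);
    int r = build(ridx, depth + 1);
    nodes[node_id].feature = best_feat;
    nodes[node_id].threshold = best_thr;
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int maxdepth, int minsplit, int seed) {
  int n = X.nrow();
  std::mt19937 rng((unsigned)seed);
  List forest(ntree);
  std::uniform_int_distribution<int> boot(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = boot(rng);
    TreeBuilder tb(X, y, mtry, maxdepth, minsplit, rng);
    tb.build(idx, 0);
    int m = (int)tb.nodes.size();
    NumericMatrix tree(m, 5);  // feature, threshold, left, right, value
    for (int k = 0; k < m; ++k) {
      tree(k, 0) = tb.nodes[k].feature;
      tree(k, 1) = tb.nodes[k].threshold;
      tree(k, 2) = tb.nodes[k].left;
      tree(k, 3) = tb.nodes[k].right;
      tree(k, 4) = tb.nodes[k].value;
    }
    forest[t] = tree;
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  int n = X.nrow(), T = forest.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while ((int)tree(k, 0) >= 0) {
        int j = (int)tree(k, 0);
        k = X(i, j) <= tree(k, 1) ? (int)tree(k, 2) : (int)tree(k, 3);
      }
      out[i] += tree(k, 4);
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= T;
  return out;
}
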