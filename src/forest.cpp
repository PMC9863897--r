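#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bagged CART regression trees (variance-reduction splits, min-leaf
// control). Each tree is flattened to a numeric matrix with one row per
// node: [feature(1-based, 0=leaf), threshold, left, right, value]
// where left/right are 1-based row indices into the same matrix.

struct TreeBuilder {
  const NumericMatrix& X;
  const NumericVector& y;
  int min_leaf;
  int max_depth;
  std::vector<double> feat, thr, val;
  std::vector<int> left, right;

  TreeBuilder(const NumericMatrix& X_, const NumericVector& y_,
              int min_leaf_, int max_depth_)
    : X(X_), y(y_), min_leaf(min_leaf_), max_depth(max_depth_) {}

  int build(std::vector<int>& idx, int depth) {
    int node = (int)feat.size();
    feat.push_back(0.0); thr.push_back(0.0);
    left.push_back(0); right.push_back(0);
    double mean = 0.0;
    for (int i : idx) mean += y[i];
    mean /= idx.size();
    val.push_back(mean);

    int n = (int)idx.size();
    if (n < 2 * min_leaf || depth >= max_depth) return node;

    // current node SSE (for improvement check)
    double sse = 0.0;
    for (int i : idx) { double d = y[i] - mean; sse += d * d; }
    if (sse <= 1e-12) return node;

    int best_f = -1;
    double best_thr = 0.0, best_score = sse;
    int p = X.ncol();
    std::vector<int> ord(idx);
    for (int f = 0; f < p; ++f) {
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return X(a, f) < X(b, f);
      });
      // prefix sums over sorted order
      double sl = 0.0, sl2 = 0.0;
      double st = 0.0, st2 = 0.0;
      for (int i : ord) { st += y[i]; st2 += y[i] * y[i]; }
      for (int k = 0; k < n - 1; ++k) {
        double yi = y[ord[k]];
        sl += yi; sl2 += yi * yi;
        int nl = k + 1, nr = n - nl;
        if (nl < min_leaf || nr < min_leaf) continue;
        if (X(ord[k], f) == X(ord[k + 1], f)) continue;  // no valid cut here
        double sr = st - sl, sr2 = st2 - sl2;
        double score = (sl2 - sl * sl / nl) + (sr2 - sr * sr / nr);
        if (score < best_score - 1e-12) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (X(ord[k], f) + X(ord[k + 1], f));
        }
      }
    }
    if (best_f < 0) return node;

    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    feat[node] = best_f + 1;
    thr[node] = best_thr;
    left[node] = build(li, depth + 1) + 1;
    right[node] = build(ri, depth + 1) + 1;
    return node;
  }

  NumericMatrix flatten() {
    int m = (int)feat.size();
    NumericMatrix out(m, 5);
    for (int i = 0; i < m; ++i) {
      out(i, 0) = feat[i]; out(i, 1) = thr[i];
      out(i, 2) = left[i]; out(i, 3) = right[i]; out(i, 4) = val[i];
    }
    return out;
  }
};

// [[Rcpp::export]]
List forest_fit(NumericMatrix X, NumericVector y, IntegerMatrix boot,
                int min_leaf, int max_depth = 12) {
  int n_trees = boot.ncol();
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(boot.nrow());
    for (int i = 0; i < boot.nrow(); ++i) idx[i] = boot(i, t) - 1;
    TreeBuilder tb(X, y, min_leaf, max_depth);
    std::vector<int> root_idx(idx);
    tb.build(root_idx, 0);
    trees[t] = tb.flatten();
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector forest_predict(List trees, NumericMatrix X) {
  int n = X.nrow(), n_trees = trees.size();
  NumericVector out(n);
  for (int t = 0; t < n_trees; ++t) {
    NumericMatrix tr = trees[t];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr(node, 0) > 0) {
        int f = (int)tr(node, 0) - 1;
        node = (X(i, f) <= tr(node, 1)) ? (int)tr(node, 2) - 1
                                        : (int)tr(node, 3) - 1;
      }
      out[i] += tr(node, 4);
    }
  }
  return out / n_trees;
}
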