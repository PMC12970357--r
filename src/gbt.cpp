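#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted least-squares regression tree used as the base learner of the
// gradient-boosted classifier. Greedy CART growth: each node's split
// maximises the reduction in weighted squared error of the response
// (the boosting pseudo-residuals); thresholds are midpoints between
// distinct consecutive feature values.

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child node ids
  double value;     // weighted mean response (leaf prediction)
};

static void grow(const NumericMatrix& X, const NumericVector& r,
                 const NumericVector& w, std::vector<int>& idx,
                 int depth, int max_depth, int min_leaf,
                 std::vector<Node>& nodes, int node_id) {
  const int n = idx.size(), p = X.ncol();
  double W = 0.0, S = 0.0;
  for (int i : idx) { W += w[i]; S += w[i] * r[i]; }
  nodes[node_id].value = (W > 0.0) ? S / W : 0.0;
  nodes[node_id].feature = -1;
  if (depth >= max_depth || n < 2 * min_leaf) return;

  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx);
  std::vector<int> best_ord;
  for (int f = 0; f < p; ++f) {
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, f) < X(b, f); });
    double WL = 0.0, SL = 0.0;
    for (int j = 0; j < n - 1; ++j) {
      int i = ord[j];
      WL += w[i]; SL += w[i] * r[i];
      if (X(ord[j], f) == X(ord[j + 1], f)) continue;
      if (j + 1 < min_leaf || n - j - 1 < min_leaf) continue;
      double WR = W - WL, SR = S - SL;
      if (WL <= 0.0 || WR <= 0.0) continue;
      double gain = SL * SL / WL + SR * SR / WR - S * S / W;
      if (gain > best_gain) {
        best_gain = gain; best_f = f; best_pos = j;
        best_thr = 0.5 * (X(ord[j], f) + X(ord[j + 1], f));
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> li(best_ord.begin(), best_ord.begin() + best_pos + 1);
  std::vector<int> ri(best_ord.begin() + best_pos + 1, best_ord.end());
  int lid = nodes.size(); nodes.push_back(Node());
  int rid = nodes.size(); nodes.push_back(Node());
  nodes[node_id].feature = best_f;
  nodes[node_id].threshold = best_thr;
  nodes[node_id].left = lid;
  nodes[node_id].right = rid;
  grow(X, r, w, li, depth + 1, max_depth, min_leaf, nodes, lid);
  grow(X, r, w, ri, depth + 1, max_depth, min_leaf, nodes, rid);
}

// [[Rcpp::export]]
List gbt_grow_tree(NumericMatrix X, NumericVector r, NumericVector w,
                   int max_depth, int min_leaf) {
  std::vector<Node> nodes;
  nodes.push_back(Node());
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  grow(X, r, w, idx, 0, max_depth, min_leaf, nodes, 0);
  int m = nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

// [[Rcpp::export]]
IntegerVector gbt_leaf_index(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = node + 1;  // 1-based for R
  }
  return out;
}
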