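// Minimal CART regression tree used as the base learner for the bagged
// (random-forest style) and boosted (BRT style) presence-background
// models. Greedy variance-reduction splits; feature subsampling uses R's
// RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Node {
  int feature = -1;      // -1 = leaf
  double threshold = 0.0;
  double value = 0.0;    // leaf mean
  int left = -1, right = -1;
};

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& idx, int lo, int hi, int depth,
                 int mtry, int min_node, int max_depth,
                 std::vector<Node>& nodes, int node_id) {
  int n = hi - lo;
  double sum = 0.0, sum2 = 0.0;
  for (int k = lo; k < hi; ++k) { sum += y[idx[k]]; sum2 += y[idx[k]] * y[idx[k]]; }
  double mean = sum / n;
  nodes[node_id].value = mean;
  double sse = sum2 - sum * mean;
  if (depth >= max_depth || n < 2 * min_node || sse <= 1e-12) return;

  int p = X.ncol();
  // sample mtry distinct features via partial Fisher-Yates (R RNG)
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int m = std::min(mtry, p);
  for (int j = 0; j < m; ++j) {
    int r = j + (int)std::floor(unif_rand() * (p - j));
    if (r >= p) r = p - 1;
    std::swap(feats[j], feats[r]);
  }

  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  std::vector<std::pair<double,double> > vals(n);
  for (int jj = 0; jj < m; ++jj) {
    int f = feats[jj];
    for (int k = 0; k < n; ++k)
      vals[k] = std::make_pair(X(idx[lo + k], f), y[idx[lo + k]]);
    std::sort(vals.begin(), vals.end());
    if (vals[0].first == vals[n - 1].first) continue;
    double lsum = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      lsum += vals[k].second;
      if (vals[k].first == vals[k + 1].first) continue;
      int nl = k + 1, nr = n - nl;
      if (nl < min_node || nr < min_node) continue;
      double rsum = sum - lsum;
      double gain = lsum * lsum / nl + rsum * rsum / nr - sum * mean;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo, hi) by the chosen split
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (X(idx[k], best_f) <= best_thr) std::swap(idx[k], idx[mid++]);
  if (mid == lo || mid == hi) return;

  nodes[node_id].feature = best_f;
  nodes[node_id].threshold = best_thr;
  int l = (int)nodes.size(); nodes.push_back(Node());
  int r = (int)nodes.size(); nodes.push_back(Node());
  nodes[node_id].left = l;
  nodes[node_id].right = r;
  grow(X, y, idx, lo, mid, depth + 1, mtry, min_node, max_depth, nodes, l);
  grow(X, y, idx, mid, hi, depth + 1, mtry, min_node, max_depth, nodes, r);
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, IntegerVector rows,
                   int mtry, int min_node, int max_depth) {
  std::vector<int> idx(rows.size());
  for (int i = 0; i < rows.size(); ++i) idx[i] = rows[i] - 1;
  std::vector<Node> nodes(1);
  GetRNGstate();
  grow(X, y, idx, 0, (int)idx.size(), 0, mtry, min_node, max_depth, nodes, 0);
  PutRNGstate();
  int nn = (int)nodes.size();
  IntegerVector feature(nn), left(nn), right(nn);
  NumericVector thr(nn), value(nn);
  for (int i = 0; i < nn; ++i) {
    feature[i] = nodes[i].feature;
    thr[i] = nodes[i].threshold;
    value[i] = nodes[i].value;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
  }
  return List::create(_["feature"] = feature, _["threshold"] = thr,
                      _["value"] = value, _["left"] = left,
                      _["right"] = right);
}

// [[Rcpp::export]]
IntegerVector cpp_tree_leaf(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"];
  NumericVector thr = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = node + 1; // 1-based
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tree_predict(List tree, NumericMatrix X) {
  NumericVector value = tree["value"];
  IntegerVector leaf = cpp_tree_leaf(tree, X);
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = value[leaf[i] - 1];
  return out;
}
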