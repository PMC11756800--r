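#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Depth-limited regression tree on quantile-binned features, used as the
// boosting base learner.  Splits maximize the weighted decrease in squared
// error (w_L w_R / (w_L + w_R) * (mean_L - mean_R)^2, the Friedman MSE
// improvement for unit weights).  Features are pre-binned once per
// training run, so each stage costs O(n * d + nodes * d * bins).
//
// Node encoding (columns of the returned matrix):
//   feature (0-based, -1 for leaf), bin threshold (go left if bin <= thr),
//   left child, right child, value.

struct BuildNode {
  std::vector<int> rows;
  int depth;
  int index;
};

// [[Rcpp::export]]
NumericMatrix cart_fit_cpp(IntegerMatrix xb, NumericVector y,
                           int max_depth, int n_bins) {
  const int n = xb.nrow(), d = xb.ncol();
  std::vector<std::array<double, 5>> nodes;
  std::vector<BuildNode> stack;
  {
    BuildNode root;
    root.rows.resize(n);
    for (int i = 0; i < n; ++i) root.rows[i] = i;
    root.depth = 0;
    root.index = 0;
    nodes.push_back({{-1, 0, -1, -1, 0}});
    stack.push_back(std::move(root));
  }
  std::vector<double> bin_sum(n_bins);
  std::vector<int> bin_cnt(n_bins);
  while (!stack.empty()) {
    BuildNode nd = std::move(stack.back());
    stack.pop_back();
    const int m = nd.rows.size();
    double tot = 0;
    for (int r : nd.rows) tot += y[r];
    const double mean = tot / m;
    nodes[nd.index][4] = mean;
    if (nd.depth >= max_depth || m < 2) continue;
    // find the best binned split across features
    double best_gain = 1e-12;
    int best_f = -1, best_b = -1;
    for (int f = 0; f < d; ++f) {
      std::fill(bin_sum.begin(), bin_sum.end(), 0.0);
      std::fill(bin_cnt.begin(), bin_cnt.end(), 0);
      for (int r : nd.rows) {
        const int b = xb(r, f);
        bin_sum[b] += y[r];
        bin_cnt[b] += 1;
      }
      double ls = 0;
      int lc = 0;
      for (int b = 0; b < n_bins - 1; ++b) {
        ls += bin_sum[b];
        lc += bin_cnt[b];
        if (lc == 0 || lc == m) continue;
        const int rc = m - lc;
        const double rs = tot - ls;
        const double dm = ls / lc - rs / rc;
        const double gain = (double)lc * rc / m * dm * dm;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_b = b;
        }
      }
    }
    if (best_f < 0) continue;
    BuildNode left, right;
    left.depth = right.depth = nd.depth + 1;
    for (int r : nd.rows) {
      if (xb(r, best_f) <= best_b) left.rows.push_back(r);
      else right.rows.push_back(r);
    }
    left.index = nodes.size();
    nodes.push_back({{-1, 0, -1, -1, 0}});
    right.index = nodes.size();
    nodes.push_back({{-1, 0, -1, -1, 0}});
    nodes[nd.index][0] = best_f;
    nodes[nd.index][1] = best_b;
    nodes[nd.index][2] = left.index;
    nodes[nd.index][3] = right.index;
    stack.push_back(std::move(left));
    stack.push_back(std::move(right));
  }
  NumericMatrix out(nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    for (int j = 0; j < 5; ++j) out(i, j) = nodes[i][j];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cart_predict_cpp(NumericMatrix tree, IntegerMatrix xb) {
  const int n = xb.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (tree(node, 0) >= 0) {
      const int f = (int)tree(node, 0);
      node = (xb(i, f) <= (int)tree(node, 1)) ? (int)tree(node, 2)
                                              : (int)tree(node, 3);
    }
    out[i] = tree(node, 4);
  }
  return out;
}

// Map raw feature values to bin indices given per-feature edge vectors
// (list of ascending numeric vectors; bin = #edges < value).
// [[Rcpp::export]]
IntegerMatrix cart_bin_cpp(NumericMatrix x, List edges) {
  const int n = x.nrow(), d = x.ncol();
  IntegerMatrix out(n, d);
  for (int f = 0; f < d; ++f) {
    NumericVector e = edges[f];
    const int ne = e.size();
    for (int i = 0; i < n; ++i) {
      const double v = x(i, f);
      // binary search: count of edges <= v
      int lo = 0, hi = ne;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (e[mid] <= v) lo = mid + 1; else hi = mid;
      }
      out(i, f) = lo;
    }
  }
  return out;
}
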