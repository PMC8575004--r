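// CART regression trees with bagging (random-forest style: bootstrap +
// per-split feature subsampling) and shrinkage boosting (gradient boosting
// with squared loss, row subsampling and depth-limited trees). Written
// against R's RNG so set.seed() in R makes fits bit-reproducible.
//
// A fitted tree is a numeric matrix with one row per node and columns
// {feature (0-based, -1 for leaf), threshold, left, right, value}.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // child node indices (0-based), -1 for leaf
  double value;     // node mean of y
};

struct StackItem {
  int lo, hi;   // [lo, hi) range into samp
  int node;     // node index
  int depth;
};

// sample `k` distinct integers from 0..n-1 (partial Fisher-Yates, R RNG)
inline void sample_without_replacement(std::vector<int>& pool, int k) {
  const int n = static_cast<int>(pool.size());
  for (int i = 0; i < k; ++i) {
    int j = i + static_cast<int>(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
  }
}

// Column-major copy of X for cache-friendly split scans.
struct Cols {
  int n, p;
  std::vector<double> v;
  explicit Cols(const NumericMatrix& X)
      : n(X.nrow()), p(X.ncol()), v(X.begin(), X.end()) {}
  inline double at(int row, int col) const { return v[col * (size_t)n + row]; }
};

// Build one CART regression tree on rows samp[lo..hi) of X.
// Splits maximise the decrease in residual sum of squares, i.e. maximise
// sum_l^2/n_l + sum_r^2/n_r. Nodes with n <= min_node (or at max_depth,
// or with no admissible split) become leaves.
std::vector<Node> build_tree(const Cols& X, const double* y,
                             std::vector<int>& samp, int mtry, int min_node,
                             int max_depth) {
  const int p = X.p;
  std::vector<Node> nodes;
  std::vector<StackItem> stack;
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double, double>> xy;

  nodes.push_back(Node());
  stack.push_back({0, static_cast<int>(samp.size()), 0, 0});

  while (!stack.empty()) {
    StackItem it = stack.back();
    stack.pop_back();
    const int n = it.hi - it.lo;

    double sum = 0.0;
    for (int i = it.lo; i < it.hi; ++i) sum += y[samp[i]];
    Node& nd = nodes[it.node];
    nd.feature = -1;
    nd.threshold = 0.0;
    nd.left = nd.right = -1;
    nd.value = sum / n;

    if (n <= min_node || (max_depth > 0 && it.depth >= max_depth)) continue;

    for (int f = 0; f < p; ++f) feat_pool[f] = f;
    sample_without_replacement(feat_pool, mtry);

    int best_feat = -1;
    double best_score = -1.0, best_thr = 0.0;
    const double parent_score = sum * sum / n;

    for (int fi = 0; fi < mtry; ++fi) {
      const int f = feat_pool[fi];
      xy.resize(n);
      for (int i = 0; i < n; ++i) {
        const int r = samp[it.lo + i];
        xy[i] = {X.at(r, f), y[r]};
      }
      std::sort(xy.begin(), xy.end());
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += xy[i].second;
        if (xy[i].first >= xy[i + 1].first) continue;  // ties: no split here
        const int nl = i + 1, nr = n - nl;
        const double sr = sum - sl;
        const double score = sl * sl / nl + sr * sr / nr;
        if (score > best_score) {
          best_score = score;
          best_feat = f;
          best_thr = (xy[i].first + xy[i + 1].first) / 2.0;
        }
      }
    }

    if (best_feat < 0 || best_score <= parent_score + 1e-12) continue;

    // in-place partition of the sample range
    int mid = it.lo;
    for (int i = it.lo; i < it.hi; ++i) {
      if (X.at(samp[i], best_feat) <= best_thr) {
        std::swap(samp[i], samp[mid]);
        ++mid;
      }
    }
    if (mid == it.lo || mid == it.hi) continue;  // degenerate (shouldn't happen)

    const int left_id = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    const int right_id = static_cast<int>(nodes.size());
    nodes.push_back(Node());
    Node& nd2 = nodes[it.node];  // re-take reference: vector may have grown
    nd2.feature = best_feat;
    nd2.threshold = best_thr;
    nd2.left = left_id;
    nd2.right = right_id;
    stack.push_back({it.lo, mid, left_id, it.depth + 1});
    stack.push_back({mid, it.hi, right_id, it.depth + 1});
  }
  return nodes;
}

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix out(static_cast<int>(nodes.size()), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value");
  return out;
}

inline double tree_predict_row(const NumericMatrix& tree,
                               const NumericMatrix& X, int row) {
  int node = 0;
  while (true) {
    const int f = static_cast<int>(tree(node, 0));
    if (f < 0) return tree(node, 4);
    node = (X(row, f) <= tree(node, 1))
               ? static_cast<int>(tree(node, 2))
               : static_cast<int>(tree(node, 3));
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix fit_tree_cpp(NumericMatrix X, NumericVector y, int mtry,
                           int min_node, int max_depth) {
  const int n = X.nrow();
  Cols cols(X);
  std::vector<int> samp(n);
  for (int i = 0; i < n; ++i) samp[i] = i;
  return pack_tree(build_tree(cols, &y[0], samp, mtry, min_node, max_depth));
}

// [[Rcpp::export]]
List fit_forest_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int min_node) {
  const int n = X.nrow();
  Cols cols(X);
  List trees(ntree);
  std::vector<int> samp(n);
  for (int t = 0; t < ntree; ++t) {
    for (int i = 0; i < n; ++i) {
      int j = static_cast<int>(unif_rand() * n);
      if (j >= n) j = n - 1;
      samp[i] = j;  // bootstrap with replacement
    }
    trees[t] = pack_tree(build_tree(cols, &y[0], samp, mtry, min_node, 0));
  }
  return trees;
}

// [[Rcpp::export]]
List fit_gbm_cpp(NumericMatrix X, NumericVector y, int nrounds, double eta,
                 int max_depth, double subsample, int min_node) {
  const int n = X.nrow();
  const int p = X.ncol();
  Cols cols(X);
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;

  std::vector<double> fhat(n, init);
  NumericVector resid(n);
  List trees(nrounds);
  std::vector<int> pool(n);
  const int m = std::max(2, static_cast<int>(std::floor(subsample * n)));

  for (int t = 0; t < nrounds; ++t) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fhat[i];
    for (int i = 0; i < n; ++i) pool[i] = i;
    sample_without_replacement(pool, m);
    std::vector<int> samp(pool.begin(), pool.begin() + m);
    NumericMatrix tree =
        pack_tree(build_tree(cols, &resid[0], samp, p, min_node, max_depth));
    for (int i = 0; i < n; ++i) {
      fhat[i] += eta * tree_predict_row(tree, X, i);
    }
    trees[t] = tree;
  }
  return List::create(Named("init") = init, Named("trees") = trees);
}

// [[Rcpp::export]]
NumericVector predict_trees_cpp(List trees, NumericMatrix X, bool average,
                                double init, double eta) {
  const int n = X.nrow();
  const int nt = trees.size();
  NumericVector out(n, init);
  for (int t = 0; t < nt; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) {
      out[i] += eta * tree_predict_row(tree, X, i);
    }
  }
  if (average && nt > 0) {
    for (int i = 0; i < n; ++i) out[i] = (out[i] - init) / nt + init;
  }
  return out;
}
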