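// Exact-greedy regression tree induction for second-order gradient
// boosting. Each node split maximizes the usual structure-score gain
//   0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)) - gamma
// and leaf weights are -G/(H+lambda). Fully deterministic: ties resolve
// to the lowest feature index and lowest threshold.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  int left, right;  // node indices, -1 for leaf
  double value;
};

static void grow(const NumericMatrix &X, const NumericVector &grad,
                 const NumericVector &hess, std::vector<int> &idx,
                 int depth, int max_depth, double lambda, double gamma,
                 double min_child_weight, std::vector<Node> &nodes,
                 int node_id) {
  const int n = idx.size();
  double G = 0.0, H = 0.0;
  for (int k = 0; k < n; ++k) {
    G += grad[idx[k]];
    H += hess[idx[k]];
  }
  nodes[node_id].value = -G / (H + lambda);
  nodes[node_id].feature = -1;
  nodes[node_id].left = nodes[node_id].right = -1;
  if (depth >= max_depth || n < 2) return;

  const double parent_score = G * G / (H + lambda);
  double best_gain = 0.0;
  int best_feature = -1;
  double best_threshold = 0.0;

  const int p = X.ncol();
  std::vector<int> ord(idx);
  for (int j = 0; j < p; ++j) {
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return X(a, j) < X(b, j); });
    double GL = 0.0, HL = 0.0;
    for (int k = 0; k + 1 < n; ++k) {
      GL += grad[ord[k]];
      HL += hess[ord[k]];
      const double x1 = X(ord[k], j), x2 = X(ord[k + 1], j);
      if (x2 <= x1) continue;  // no split between equal values
      const double GR = G - GL, HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      const double gain =
          0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                 parent_score) - gamma;
      if (gain > best_gain + 1e-12) {
        best_gain = gain;
        best_feature = j;
        best_threshold = 0.5 * (x1 + x2);
      }
    }
  }
  if (best_feature < 0) return;

  std::vector<int> left_idx, right_idx;
  for (int k = 0; k < n; ++k) {
    if (X(idx[k], best_feature) < best_threshold)
      left_idx.push_back(idx[k]);
    else
      right_idx.push_back(idx[k]);
  }
  if (left_idx.empty() || right_idx.empty()) return;

  nodes[node_id].feature = best_feature;
  nodes[node_id].threshold = best_threshold;
  nodes.push_back(Node());
  const int left_id = nodes.size() - 1;
  nodes.push_back(Node());
  const int right_id = nodes.size() - 1;
  nodes[node_id].left = left_id;
  nodes[node_id].right = right_id;
  grow(X, grad, hess, left_idx, depth + 1, max_depth, lambda, gamma,
       min_child_weight, nodes, left_id);
  grow(X, grad, hess, right_idx, depth + 1, max_depth, lambda, gamma,
       min_child_weight, nodes, right_id);
}

// [[Rcpp::export]]
NumericMatrix fit_tree_cpp(NumericMatrix X, NumericVector grad,
                           NumericVector hess, int max_depth, double lambda,
                           double gamma, double min_child_weight) {
  std::vector<Node> nodes;
  nodes.push_back(Node());
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  grow(X, grad, hess, idx, 0, max_depth, lambda, gamma, min_child_weight,
       nodes, 0);
  NumericMatrix out(nodes.size(), 5);
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

static double predict_one(const NumericMatrix &tree, const NumericMatrix &X,
                          int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    const int f = static_cast<int>(tree(node, 0));
    node = X(row, f) < tree(node, 1) ? static_cast<int>(tree(node, 2))
                                     : static_cast<int>(tree(node, 3));
  }
  return tree(node, 4);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(NumericMatrix X, List trees,
                                 double base_score, double learning_rate,
                                 int n_trees) {
  const int n = X.nrow();
  NumericVector out(n, base_score);
  const int limit = n_trees < 0 ? trees.size() : n_trees;
  for (int t = 0; t < limit; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i)
      out[i] += learning_rate * predict_one(tree, X, i);
  }
  return out;
}
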