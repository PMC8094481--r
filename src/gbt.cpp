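// Second-order gradient-boosted regression trees (squared loss).
// Exact greedy splits with the regularised gain
//   0.5 * [GL^2/(HL+lambda) + GR^2/(HR+lambda) - G^2/(H+lambda)] - gamma,
// leaf weight -G/(H+lambda), learning-rate shrinkage, per-tree row
// subsampling and column subsampling with a private seeded RNG.

#include <Rcpp.h>
#include <algorithm>
#include <random>
#include <vector>

using namespace Rcpp;

struct Node {
  int feature = -1;       // -1 => leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  double value = 0.0;     // leaf weight (already shrunk)
};

struct Tree {
  std::vector<Node> nodes;
  int add(const Node& nd) {
    nodes.push_back(nd);
    return (int)nodes.size() - 1;
  }
  double predict_row(const NumericMatrix& X, int i) const {
    int k = 0;
    while (nodes[k].feature >= 0) {
      k = (X(i, nodes[k].feature) < nodes[k].threshold) ? nodes[k].left
                                                        : nodes[k].right;
    }
    return nodes[k].value;
  }
};

struct SplitInfo {
  double gain = 0.0;
  int feature = -1;
  double threshold = 0.0;
};

static SplitInfo best_split(const NumericMatrix& X,
                            const std::vector<double>& grad,
                            const std::vector<int>& rows,
                            const std::vector<int>& feats, double lambda,
                            double gamma, double min_child_weight) {
  SplitInfo best;
  const int n = (int)rows.size();
  double G = 0.0;
  for (int r : rows) G += grad[r];
  const double H = (double)n;  // squared loss: hessian = 1 per row
  const double parent = G * G / (H + lambda);

  std::vector<std::pair<double, double> > vals(n);  // (x, g)
  for (int f : feats) {
    for (int j = 0; j < n; ++j) {
      vals[j] = std::make_pair(X(rows[j], f), grad[rows[j]]);
    }
    std::sort(vals.begin(), vals.end());
    double GL = 0.0, HL = 0.0;
    for (int j = 0; j < n - 1; ++j) {
      GL += vals[j].second;
      HL += 1.0;
      if (vals[j].first == vals[j + 1].first) continue;
      double HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double GR = G - GL;
      double gain = 0.5 * (GL * GL / (HL + lambda) + GR * GR / (HR + lambda) -
                           parent) - gamma;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = f;
        best.threshold = 0.5 * (vals[j].first + vals[j + 1].first);
      }
    }
  }
  return best;
}

static int grow(Tree& tree, const NumericMatrix& X,
                const std::vector<double>& grad, std::vector<int>& rows,
                const std::vector<int>& feats, int depth, int max_depth,
                double lambda, double gamma, double min_child_weight,
                double eta) {
  double G = 0.0;
  for (int r : rows) G += grad[r];
  double H = (double)rows.size();

  SplitInfo sp;
  if (depth < max_depth && rows.size() >= 2) {
    sp = best_split(X, grad, rows, feats, lambda, gamma, min_child_weight);
  }
  if (sp.feature < 0) {
    Node leaf;
    leaf.value = -eta * G / (H + lambda);
    return tree.add(leaf);
  }
  std::vector<int> lrows, rrows;
  for (int r : rows) {
    if (X(r, sp.feature) < sp.threshold) lrows.push_back(r);
    else rrows.push_back(r);
  }
  Node nd;
  nd.feature = sp.feature;
  nd.threshold = sp.threshold;
  int self = tree.add(nd);
  int li = grow(tree, X, grad, lrows, feats, depth + 1, max_depth, lambda,
                gamma, min_child_weight, eta);
  int ri = grow(tree, X, grad, rrows, feats, depth + 1, max_depth, lambda,
                gamma, min_child_weight, eta);
  tree.nodes[self].left = li;
  tree.nodes[self].right = ri;
  return self;
}

static List tree_to_list(const Tree& t) {
  int m = (int)t.nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = t.nodes[i].feature;
    threshold[i] = t.nodes[i].threshold;
    left[i] = t.nodes[i].left;
    right[i] = t.nodes[i].right;
    value[i] = t.nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right,
                      _["value"] = value);
}

// [[Rcpp::export]]
List gbt_train_cpp(NumericMatrix X, NumericVector y, int n_estimators,
                   int max_depth, double min_child_weight, double gamma,
                   double subsample, double colsample_bytree,
                   double learning_rate, double lambda, int seed) {
  const int n = X.nrow(), p = X.ncol();
  double base = mean(y);
  std::vector<double> pred(n, base), grad(n);
  std::mt19937 rng((unsigned)seed);

  List trees(n_estimators);
  for (int it = 0; it < n_estimators; ++it) {
    for (int i = 0; i < n; ++i) grad[i] = pred[i] - y[i];

    std::vector<int> rows(n), feats(p);
    for (int i = 0; i < n; ++i) rows[i] = i;
    for (int f = 0; f < p; ++f) feats[f] = f;
    if (subsample < 1.0) {
      std::shuffle(rows.begin(), rows.end(), rng);
      rows.resize(std::max(2, (int)std::floor(subsample * n)));
      std::sort(rows.begin(), rows.end());
    }
    if (colsample_bytree < 1.0) {
      std::shuffle(feats.begin(), feats.end(), rng);
      feats.resize(std::max(1, (int)std::floor(colsample_bytree * p)));
      std::sort(feats.begin(), feats.end());
    }

    Tree tree;
    grow(tree, X, grad, rows, feats, 0, max_depth, lambda, gamma,
         min_child_weight, learning_rate);
    for (int i = 0; i < n; ++i) pred[i] += tree.predict_row(X, i);
    trees[it] = tree_to_list(tree);
  }
  return List::create(_["base_score"] = base, _["trees"] = trees);
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X,
                              int n_trees = -1) {
  List trees = model["trees"];
  double base = as<double>(model["base_score"]);
  int nt = (n_trees < 0) ? trees.size() : std::min<int>(n_trees, trees.size());
  const int n = X.nrow();
  NumericVector out(n, base);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    IntegerVector feature = tl["feature"], left = tl["left"],
                  right = tl["right"];
    NumericVector threshold = tl["threshold"], value = tl["value"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (feature[k] >= 0) {
        k = (X(i, feature[k]) < threshold[k]) ? left[k] : right[k];
      }
      out[i] += value[k];
    }
  }
  return out;
}
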