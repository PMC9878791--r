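// Random-forest classifier: bagged CART trees, Gini impurity, per-node
// feature subsampling (mtry), out-of-bag votes and mean-decrease-in-impurity
// importance. Uses R's RNG so results are reproducible under set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  int leaf_class = 0;
};

double gini(const std::vector<int> &counts, int n) {
  if (n == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double p = double(c) / n;
    g -= p * p;
  }
  return g;
}

int majority(const std::vector<int> &counts) {
  return int(std::max_element(counts.begin(), counts.end()) - counts.begin());
}

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int K, mtry, min_node;
  std::vector<Node> nodes;
  std::vector<double> &importance;   // accumulated impurity decrease

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_, int K_,
              int mtry_, int min_node_, std::vector<double> &imp)
      : X(X_), y(y_), K(K_), mtry(mtry_), min_node(min_node_),
        importance(imp) {}

  int build(std::vector<int> &idx) {
    int n = idx.size();
    std::vector<int> counts(K, 0);
    for (int i : idx) counts[y[i]]++;
    double g0 = gini(counts, n);

    Node node;
    node.leaf_class = majority(counts);
    int me = nodes.size();
    nodes.push_back(node);
    if (n < 2 * min_node || g0 <= 0.0) return me;

    // sample mtry distinct features (partial Fisher-Yates on R's RNG)
    int p = X.ncol();
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + int(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }

    int best_f = -1;
    double best_thr = 0.0, best_dec = 1e-12;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::vector<int> left(K, 0), right = counts;
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        left[vals[i].second]++;
        right[vals[i].second]--;
        nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        if (nl < min_node || n - nl < min_node) continue;
        double dec = g0 - (nl * gini(left, nl) +
                           (n - nl) * gini(right, n - nl)) / n;
        if (dec > best_dec) {
          best_dec = dec;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return me;

    importance[best_f] += best_dec * n;
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    nodes[me].feature = best_f;
    nodes[me].threshold = best_thr;
    int l = build(li);
    int r = build(ri);
    nodes[me].feature = best_f;   // vector may have reallocated
    nodes[me].threshold = best_thr;
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }

  int predict_row(const NumericMatrix &M, int i) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      cur = (M(i, nodes[cur].feature) <= nodes[cur].threshold)
                ? nodes[cur].left : nodes[cur].right;
    }
    return nodes[cur].leaf_class;
  }
};

} // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int n_classes, int n_trees,
            int mtry, int min_node, Nullable<NumericMatrix> X_test) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  IntegerMatrix oob_votes(n, n_classes);
  IntegerMatrix test_votes;
  bool has_test = X_test.isNotNull();
  NumericMatrix Xt;
  if (has_test) {
    Xt = NumericMatrix(X_test);
    test_votes = IntegerMatrix(Xt.nrow(), n_classes);
  }

  for (int t = 0; t < n_trees; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int k = int(unif_rand() * n);
      if (k >= n) k = n - 1;
      idx[i] = k;
      inbag[k] = 1;
    }
    TreeBuilder tb(X, y, n_classes, mtry, min_node, importance);
    tb.build(idx);
    for (int i = 0; i < n; ++i) {
      if (!inbag[i]) oob_votes(i, tb.predict_row(X, i))++;
    }
    if (has_test) {
      for (int i = 0; i < Xt.nrow(); ++i) test_votes(i, tb.predict_row(Xt, i))++;
    }
  }

  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int best = -1, bc = 0;
    for (int c = 0; c < n_classes; ++c) {
      if (oob_votes(i, c) > bc) { bc = oob_votes(i, c); best = c; }
    }
    if (best >= 0) oob_pred[i] = best;
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;

  List out = List::create(_["importance"] = imp, _["oob_pred"] = oob_pred,
                          _["oob_votes"] = oob_votes);
  if (has_test) {
    IntegerVector test_pred(Xt.nrow());
    for (int i = 0; i < Xt.nrow(); ++i) {
      int best = 0;
      for (int c = 1; c < n_classes; ++c) {
        if (test_votes(i, c) > test_votes(i, best)) best = c;
      }
      test_pred[i] = best;
    }
    out["test_pred"] = test_pred;
  }
  return out;
}
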