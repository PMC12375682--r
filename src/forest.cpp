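// Bagged CART classification forest (binary labels), grown with Gini
// impurity, per-node random feature subsetting (mtry) and bootstrap
// resampling. Deterministic for a fixed seed: all randomness comes from a
// single std::mt19937 stream owned by the fit call.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Tree {
  // feat[i] == -1 marks a leaf; prob[i] is the class-1 fraction of the
  // bootstrap samples that reached the leaf.
  std::vector<int> feat;
  std::vector<double> thr;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<double> prob;

  int add_node() {
    feat.push_back(-1);
    thr.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    prob.push_back(0.0);
    return (int)feat.size() - 1;
  }
};

inline double gini_sum(double n0, double n1) {
  // n * gini = n - (n0^2 + n1^2) / n
  double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  return n - (n0 * n0 + n1 * n1) / n;
}

class Grower {
public:
  Grower(const NumericMatrix& X, const IntegerVector& y, int mtry,
         int min_node, std::mt19937& rng, std::vector<double>& importance)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node), rng_(rng),
      importance_(importance), p_((int)X.ncol()) {}

  int grow(Tree& tree, std::vector<int>& idx) {
    int node = tree.add_node();
    int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y_[i];
    int n0 = n - n1;
    tree.prob[node] = (double)n1 / (double)n;

    if (n0 == 0 || n1 == 0 || n <= min_node_) return node;

    int best_feat = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    find_best_split(idx, n0, n1, best_feat, best_thr, best_gain);
    if (best_feat < 0) return node;

    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X_(i, best_feat) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) return node;  // degenerate threshold

    importance_[best_feat] += best_gain;
    tree.feat[node] = best_feat;
    tree.thr[node] = best_thr;
    idx.clear(); idx.shrink_to_fit();
    tree.left[node] = grow(tree, li);
    tree.right[node] = grow(tree, ri);
    return node;
  }

private:
  void find_best_split(const std::vector<int>& idx, int n0, int n1,
                       int& best_feat, double& best_thr, double& best_gain) {
    int n = n0 + n1;
    double parent = gini_sum((double)n0, (double)n1);

    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p_);
    for (int j = 0; j < p_; ++j) feats[j] = j;
    for (int j = 0; j < mtry_; ++j) {
      std::uniform_int_distribution<int> d(j, p_ - 1);
      std::swap(feats[j], feats[d(rng_)]);
    }

    std::vector<std::pair<double, int>> vals(n);
    for (int fj = 0; fj < mtry_; ++fj) {
      int f = feats[fj];
      for (int k = 0; k < n; ++k)
        vals[k] = std::make_pair(X_(idx[k], f), y_[idx[k]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      double l0 = 0.0, l1 = 0.0;
      for (int k = 0; k < n - 1; ++k) {
        if (vals[k].second) l1 += 1.0; else l0 += 1.0;
        if (vals[k].first == vals[k + 1].first) continue;
        double r0 = n0 - l0, r1 = n1 - l1;
        double gain = parent - gini_sum(l0, l1) - gini_sum(r0, r1);
        if (gain > best_gain) {
          best_gain = gain;
          best_feat = f;
          best_thr = 0.5 * (vals[k].first + vals[k + 1].first);
        }
      }
    }
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  int mtry_, min_node_;
  std::mt19937& rng_;
  std::vector<double>& importance_;
  int p_;
};

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntrees, int mtry,
                int min_node, int seed) {
  int n = (int)X.nrow(), p = (int)X.ncol();
  if (n < 2) stop("need at least 2 training rows");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> draw(0, n - 1);
  std::vector<double> importance(p, 0.0);

  List trees(ntrees);
  for (int t = 0; t < ntrees; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = draw(rng);
    Tree tree;
    Grower grower(X, y, mtry, min_node, rng, importance);
    grower.grow(tree, idx);
    trees[t] = List::create(
      _["feat"] = wrap(tree.feat), _["thr"] = wrap(tree.thr),
      _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
      _["prob"] = wrap(tree.prob));
  }

  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / (double)ntrees;
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = (int)X.nrow();
  int ntrees = (int)trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntrees; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thr = tr["thr"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += prob[node];
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= (double)ntrees;
  return out;
}
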