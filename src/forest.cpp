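// A compact classification random forest: bootstrap sampling, mtry feature
// subsampling, Gini CART splits, impurity-decrease importance, and
// probability prediction by averaging leaf class distributions. Determinism
// is guaranteed by the std::mt19937 seed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
using namespace Rcpp;

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  std::vector<double> prob;
};

struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int nclass, mtry, max_depth, min_split;
  std::mt19937& rng;
  std::vector<Node> nodes;
  std::vector<double>& importance;
  int ntotal;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int nclass_,
              int mtry_, int max_depth_, int min_split_, std::mt19937& rng_,
              std::vector<double>& imp_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), max_depth(max_depth_),
        min_split(min_split_), rng(rng_), importance(imp_),
        ntotal(X_.nrow()) {}

  static double gini(const std::vector<int>& cnt, int n) {
    if (n == 0) return 0.0;
    double s = 0.0;
    for (int c : cnt) { double p = (double)c / n; s += p * p; }
    return 1.0 - s;
  }

  int build(std::vector<int>& idx, int depth) {
    int n = (int)idx.size();
    std::vector<int> cnt(nclass, 0);
    for (int i : idx) cnt[y[i]]++;
    int node_id = (int)nodes.size();
    nodes.emplace_back();
    { // leaf distribution (also kept for internal nodes; harmless)
      Node& nd = nodes[node_id];
      nd.prob.resize(nclass);
      for (int c = 0; c < nclass; ++c) nd.prob[c] = (double)cnt[c] / n;
    }
    double imp = gini(cnt, n);
    bool pure = false;
    for (int c = 0; c < nclass; ++c) if (cnt[c] == n) pure = true;
    if (pure || n < min_split || depth >= max_depth) return node_id;

    int p = X.ncol();
    // sample mtry distinct features (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; ++j) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      std::uniform_int_distribution<int> d(j, p - 1);
      std::swap(feats[j], feats[d(rng)]);
    }

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<std::pair<double, int>> vals(n);
    for (int jj = 0; jj < m; ++jj) {
      int f = feats[jj];
      for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
      std::sort(vals.begin(), vals.end());
      std::vector<int> lc(nclass, 0), rc(cnt);
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        lc[vals[i].second]++; rc[vals[i].second]--; nl++;
        if (vals[i].first == vals[i + 1].first) continue;
        double g = imp - ((double)nl / n) * gini(lc, nl)
                       - ((double)(n - nl) / n) * gini(rc, n - nl);
        if (g > best_gain) {
          best_gain = g;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node_id;

    importance[best_f] += best_gain * ((double)n / ntotal);
    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i : idx) {
      if (X(i, best_f) <= best_thr) li.push_back(i); else ri.push_back(i);
    }
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    nodes[node_id].feat = best_f;
    nodes[node_id].thr = best_thr;
    nodes[node_id].left = l;
    nodes[node_id].right = r;
    return node_id;
  }
};

static List tree_to_list(const std::vector<Node>& nodes, int nclass) {
  int nn = (int)nodes.size();
  IntegerVector feat(nn), left(nn), right(nn);
  NumericVector thr(nn);
  NumericMatrix prob(nn, nclass);
  for (int i = 0; i < nn; ++i) {
    feat[i] = nodes[i].feat;
    thr[i] = nodes[i].thr;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    for (int c = 0; c < nclass; ++c) prob(i, c) = nodes[i].prob[c];
  }
  return List::create(_["feat"] = feat, _["thr"] = thr, _["left"] = left,
                      _["right"] = right, _["prob"] = prob);
}

// [[Rcpp::export]]
List cpp_grow_forest(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                     int mtry, int max_depth, int min_split,
                     unsigned int seed) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(seed);
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  std::uniform_int_distribution<int> pick(0, n - 1);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = pick(rng);
    TreeBuilder tb(X, y, nclass, mtry, max_depth, min_split, rng, importance);
    tb.build(idx, 0);
    trees[t] = tree_to_list(tb.nodes, nclass);
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["nclass"] = nclass);
}

// [[Rcpp::export]]
NumericMatrix cpp_predict_forest(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int nclass = as<int>(forest["nclass"]);
  int n = X.nrow(), ntree = trees.size();
  NumericMatrix out(n, nclass);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"];
    NumericVector thr = tr["thr"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0) {
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      }
      for (int c = 0; c < nclass; ++c) out(i, c) += prob(node, c);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < nclass; ++c) out(i, c) /= ntree;
  return out;
}
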