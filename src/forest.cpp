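#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Classification random forest: bootstrap bagging, Gini splits on mtry
// randomly drawn predictors, majority vote, out-of-bag votes and
// mean-decrease-in-Gini importance. Deterministic given the seed (own
// xoshiro-style generator, independent of R's RNG state).

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble so small seeds give well-mixed streams
    s = seed + 0x9E3779B97F4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x9E3779B97F4A7C15ULL;
  }
  uint64_t next() {  // xorshift64*
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right, pred;
  int new_node() {
    feature.push_back(-1); thresh.push_back(0.0);
    left.push_back(-1); right.push_back(-1); pred.push_back(-1);
    return (int)feature.size() - 1;
  }
};

inline double gini_sum(const std::vector<int>& cnt, int n) {
  // n * Gini = n - sum(nk^2)/n ; return sum(nk^2) for speed
  double ss = 0.0;
  for (int k : cnt) ss += (double)k * k;
  return ss;
}

int majority(const std::vector<int>& cnt) {
  int best = 0;
  for (size_t k = 1; k < cnt.size(); ++k)
    if (cnt[k] > cnt[best]) best = (int)k;  // tie -> smallest class index
  return best;
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  int K, p, mtry, min_node;
  Rng& rng;
  Tree& tree;
  std::vector<double>& importance;
  std::vector<int> idx;                 // bootstrap sample indices, partitioned in place
  std::vector<int> feat_pool;
  std::vector<std::pair<double,int>> buf;

  int grow(int lo, int hi) {
    int node = tree.new_node();
    int n = hi - lo;
    std::vector<int> cnt(K, 0);
    for (int i = lo; i < hi; ++i) cnt[y[idx[i]]]++;
    int maj = majority(cnt);
    bool pure = (cnt[maj] == n);
    if (pure || n < 2 * min_node) { tree.pred[node] = maj; return node; }

    // draw mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    int best_f = -1; double best_t = 0.0, best_gain = 0.0;
    double parent_ss = gini_sum(cnt, n);
    for (int m = 0; m < mtry; ++m) {
      int r = m + rng.below(p - m);
      std::swap(feat_pool[m], feat_pool[r]);
      int f = feat_pool[m];
      buf.clear();
      for (int i = lo; i < hi; ++i) buf.emplace_back(X(idx[i], f), idx[i]);
      std::sort(buf.begin(), buf.end());
      if (buf.front().first == buf.back().first) continue;  // constant
      std::vector<int> lcnt(K, 0);
      double lss = 0.0, rss = parent_ss;
      int nl = 0;
      for (int i = 0; i < n - 1; ++i) {
        int cls = y[buf[i].second];
        lss += 2.0 * lcnt[cls] + 1.0;
        rss -= 2.0 * (cnt[cls] - lcnt[cls]) - 1.0;
        lcnt[cls]++; nl++;
        if (buf[i].first == buf[i + 1].first) continue;
        int nr2 = n - nl;
        if (nl < min_node || nr2 < min_node) continue;
        // decrease in (count-scaled) Gini: n*G(parent) - nl*G(l) - nr*G(r)
        double gain = lss / nl + rss / nr2 - parent_ss / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_f = f;
          best_t = 0.5 * (buf[i].first + buf[i + 1].first);
        }
      }
    }
    if (best_f < 0) { tree.pred[node] = maj; return node; }
    importance[best_f] += best_gain;
    // partition idx[lo..hi) by x <= thresh
    int i = lo, j = hi - 1;
    while (i <= j) {
      if (X(idx[i], best_f) <= best_t) ++i;
      else std::swap(idx[i], idx[j--]);
    }
    tree.feature[node] = best_f;
    tree.thresh[node] = best_t;
    int l = grow(lo, i);
    int r2 = grow(i, hi);
    tree.left[node] = l;
    tree.right[node] = r2;
    return node;
  }
};

int tree_predict(const Tree& t, const NumericMatrix& X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.thresh[node]) ? t.left[node] : t.right[node];
  return t.pred[node];
}

Tree tree_from_list(const List& tl) {
  Tree t;
  t.feature = as<std::vector<int>>(tl["feature"]);
  t.thresh  = as<std::vector<double>>(tl["thresh"]);
  t.left    = as<std::vector<int>>(tl["left"]);
  t.right   = as<std::vector<int>>(tl["right"]);
  t.pred    = as<std::vector<int>>(tl["pred"]);
  return t;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = ".rf_train")]]
List rf_train(const NumericMatrix& X, const IntegerVector& y, int nclass,
              int ntree, int mtry, int min_node, double seed) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1 || mtry > p) stop("mtry must be in [1, p]");
  Rng rng((uint64_t)seed);
  std::vector<double> importance(p, 0.0);
  IntegerMatrix oob_votes(n, nclass);
  List trees(ntree);
  std::vector<int> inbag(n);
  for (int b = 0; b < ntree; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) { int r = rng.below(n); idx[i] = r; inbag[r]++; }
    Tree tree;
    Grower g{X, y, nclass, p, mtry, min_node, rng, tree, importance,
             std::move(idx), std::vector<int>(p), {}};
    g.grow(0, n);
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob_votes(i, tree_predict(tree, X, i))++;
    trees[b] = List::create(_["feature"] = tree.feature, _["thresh"] = tree.thresh,
                            _["left"] = tree.left, _["right"] = tree.right,
                            _["pred"] = tree.pred);
  }
  NumericVector imp(importance.begin(), importance.end());
  for (int j = 0; j < p; ++j) imp[j] /= ntree;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_votes"] = oob_votes);
}

//' @noRd
// [[Rcpp::export(name = ".rf_votes")]]
IntegerMatrix rf_votes(const List& trees, const NumericMatrix& X, int nclass) {
  const int n = X.nrow(), ntree = trees.size();
  IntegerMatrix votes(n, nclass);
  for (int b = 0; b < ntree; ++b) {
    Tree t = tree_from_list(trees[b]);
    for (int i = 0; i < n; ++i) votes(i, tree_predict(t, X, i))++;
  }
  return votes;
}
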