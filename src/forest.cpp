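#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Random forest of CART trees for the pathogenicity score. Kept deliberately
// small: binary labels, numeric features, Gini impurity, per-split mtry,
// bootstrap row sampling. The ensemble score is the fraction of trees whose
// leaf majority is the pathogenic class; leaf ties vote benign (conservative).
// Uses R's RNG so results are reproducible under set.seed().

struct Tree {
  // flat arrays; feature = -1 marks a leaf, pred in {0,1}
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left, right, pred;
};

static double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p = n1 / n;
  return 2.0 * p * (1.0 - p);
}

// Fisher-Yates partial shuffle of feature indices using R's RNG
static void sample_features(std::vector<int> &feat, int mtry) {
  int p = (int)feat.size();
  for (int i = 0; i < mtry; ++i) {
    int j = i + (int)std::floor(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(feat[i], feat[j]);
  }
}

class TreeBuilder {
public:
  const NumericMatrix &X;
  const IntegerVector &y;
  int max_depth, mtry;
  double n_total;
  Tree tree;
  std::vector<double> importance; // impurity-decrease accumulator per feature

  TreeBuilder(const NumericMatrix &X_, const IntegerVector &y_,
              int max_depth_, int mtry_)
    : X(X_), y(y_), max_depth(max_depth_), mtry(mtry_),
      n_total(0.0), importance(X_.ncol(), 0.0) {}

  int build(std::vector<int> &idx, int lo, int hi, int depth) {
    int node = (int)tree.feature.size();
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);

    int n = hi - lo;
    int n1 = 0;
    for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
    // leaf vote: strict majority pathogenic, ties -> benign
    tree.pred[node] = (2 * n1 > n) ? 1 : 0;

    if (n < 2 || n1 == 0 || n1 == n || depth >= max_depth) return node;

    double g_node = gini((double)n1, (double)n);
    int p = X.ncol();
    std::vector<int> feat(p);
    for (int j = 0; j < p; ++j) feat[j] = j;
    sample_features(feat, mtry);

    int best_f = -1;
    double best_thr = 0.0, best_gain = 1e-12;
    std::vector<std::pair<double, int> > vals(n);

    for (int m = 0; m < mtry; ++m) {
      int f = feat[m];
      for (int i = 0; i < n; ++i) {
        int r = idx[lo + i];
        vals[i] = std::make_pair(X(r, f), y[r]);
      }
      std::sort(vals.begin(), vals.end());
      double l1 = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        l1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double nl = i + 1.0, nr = n - nl;
        double gain = g_node - (nl / n) * gini(l1, nl)
                             - (nr / n) * gini(n1 - l1, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return node;

    // partition idx[lo,hi) in place around the split
    std::vector<int> lft, rgt;
    lft.reserve(n); rgt.reserve(n);
    for (int i = lo; i < hi; ++i) {
      if (X(idx[i], best_f) <= best_thr) lft.push_back(idx[i]);
      else rgt.push_back(idx[i]);
    }
    if (lft.empty() || rgt.empty()) return node; // degenerate; keep leaf
    for (size_t i = 0; i < lft.size(); ++i) idx[lo + i] = lft[i];
    for (size_t i = 0; i < rgt.size(); ++i) idx[lo + lft.size() + i] = rgt[i];

    tree.feature[node] = best_f;
    tree.threshold[node] = best_thr;
    importance[best_f] += ((double)n / n_total) * best_gain;
    int mid = lo + (int)lft.size();
    tree.left[node] = build(idx, lo, mid, depth + 1);
    tree.right[node] = build(idx, mid, hi, depth + 1);
    return node;
  }
};

// [[Rcpp::export(name = ".rf_train")]]
List rf_train_cpp(NumericMatrix X, IntegerVector y, int ntree, int max_depth,
                  double sample_frac, int mtry) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  if (max_depth < 1) max_depth = 1;
  int nsamp = (int)std::floor(sample_frac * n + 0.5);
  if (nsamp < 1) nsamp = 1;

  RNGScope scope;
  List trees(ntree);
  NumericVector imp(p);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(nsamp);
    for (int i = 0; i < nsamp; ++i) { // bootstrap (with replacement)
      int j = (int)std::floor(unif_rand() * n);
      if (j >= n) j = n - 1;
      idx[i] = j;
    }
    TreeBuilder tb(X, y, max_depth, mtry);
    tb.n_total = (double)nsamp;
    tb.build(idx, 0, nsamp, 0);
    double tot = 0.0;
    for (int j = 0; j < p; ++j) tot += tb.importance[j];
    if (tot > 0.0)
      for (int j = 0; j < p; ++j) imp[j] += tb.importance[j] / tot;
    trees[t] = List::create(
      _["feature"] = wrap(tb.tree.feature),
      _["threshold"] = wrap(tb.tree.threshold),
      _["left"] = wrap(tb.tree.left),
      _["right"] = wrap(tb.tree.right),
      _["pred"] = wrap(tb.tree.pred));
  }
  // per-tree normalized impurity decreases, averaged over trees
  double s = 0.0;
  for (int j = 0; j < p; ++j) s += imp[j];
  if (s > 0.0) for (int j = 0; j < p; ++j) imp[j] /= s;
  else for (int j = 0; j < p; ++j) imp[j] = 1.0 / p; // stumpless forest
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector votes(n);
  for (int t = 0; t < ntree; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      votes[i] += pred[node];
    }
  }
  for (int i = 0; i < n; ++i) votes[i] /= ntree;
  return votes;
}
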