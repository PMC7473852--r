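#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Minimal classification random forest (bagged CART, Gini splits, random
// feature subset of size mtry at every node, trees grown to purity).
// Uses R's RNG so results are reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feat;      // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right, pred;
};

int majority(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = (int)c;
  return best;
}

// sum over classes of count^2, used to score Gini partitions
double sq_sum(const std::vector<int> &cnt) {
  double s = 0.0;
  for (size_t c = 0; c < cnt.size(); ++c) s += (double)cnt[c] * cnt[c];
  return s;
}

void grow(const NumericMatrix &X, const IntegerVector &y, int K,
          std::vector<int> &idx, int lo, int hi, int mtry, Tree &tr) {
  const int p = X.ncol();
  int node = (int)tr.feat.size();
  tr.feat.push_back(-1); tr.thresh.push_back(0.0);
  tr.left.push_back(-1); tr.right.push_back(-1); tr.pred.push_back(0);

  std::vector<int> cnt(K, 0);
  for (int t = lo; t < hi; ++t) cnt[y[idx[t]]]++;
  tr.pred[node] = majority(cnt);
  int npt = hi - lo;
  bool pure = false;
  for (int c = 0; c < K; ++c) if (cnt[c] == npt) pure = true;
  if (pure || npt < 2) return;

  // random feature subset (partial Fisher-Yates over 0..p-1)
  std::vector<int> feats(p);
  for (int f = 0; f < p; ++f) feats[f] = f;
  for (int t = 0; t < mtry; ++t) {
    int r = t + (int)std::floor(unif_rand() * (p - t));
    if (r >= p) r = p - 1;
    std::swap(feats[t], feats[r]);
  }

  double best_score = -1.0, parent_score = sq_sum(cnt) / npt;
  int best_feat = -1;
  double best_thresh = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> lcnt(K), rcnt(K);
  for (int t = 0; t < mtry; ++t) {
    int f = feats[t];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) { return X(a, f) < X(b, f); });
    std::fill(lcnt.begin(), lcnt.end(), 0);
    rcnt = cnt;
    for (int s = 0; s < npt - 1; ++s) {
      int cls = y[ord[s]];
      lcnt[cls]++; rcnt[cls]--;
      double xa = X(ord[s], f), xb = X(ord[s + 1], f);
      if (xb <= xa) continue;              // no split between equal values
      int nl = s + 1, nr2 = npt - nl;
      double score = sq_sum(lcnt) / nl + sq_sum(rcnt) / nr2;
      if (score > best_score) {
        best_score = score;
        best_feat = f;
        best_thresh = xa + (xb - xa) / 2.0;
      }
    }
  }
  if (best_feat < 0 || best_score <= parent_score + 1e-12) return;  // no useful split

  // partition idx[lo,hi) by the chosen split (stable)
  std::vector<int> lpart, rpart;
  for (int t = lo; t < hi; ++t) {
    if (X(idx[t], best_feat) <= best_thresh) lpart.push_back(idx[t]);
    else rpart.push_back(idx[t]);
  }
  if (lpart.empty() || rpart.empty()) return;
  for (size_t t = 0; t < lpart.size(); ++t) idx[lo + t] = lpart[t];
  for (size_t t = 0; t < rpart.size(); ++t) idx[lo + lpart.size() + t] = rpart[t];

  tr.feat[node] = best_feat;
  tr.thresh[node] = best_thresh;
  int mid = lo + (int)lpart.size();
  tr.left[node] = (int)tr.feat.size();
  grow(X, y, K, idx, lo, mid, mtry, tr);
  tr.right[node] = (int)tr.feat.size();
  grow(X, y, K, idx, mid, hi, mtry, tr);
}

} // namespace

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int K, int ntree, int mtry) {
  RNGScope scope;
  const int n = X.nrow();
  List forest(ntree);
  for (int b = 0; b < ntree; ++b) {
    std::vector<int> idx(n);
    for (int t = 0; t < n; ++t) {
      int r = (int)std::floor(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[t] = r;
    }
    Tree tr;
    grow(X, y, K, idx, 0, n, mtry, tr);
    forest[b] = List::create(
      _["feat"] = wrap(tr.feat), _["thresh"] = wrap(tr.thresh),
      _["left"] = wrap(tr.left), _["right"] = wrap(tr.right),
      _["pred"] = wrap(tr.pred));
  }
  return forest;
}

// Vote counts (nobs x K) across all trees.
// [[Rcpp::export]]
IntegerMatrix rf_votes_cpp(List forest, NumericMatrix X, int K) {
  const int n = X.nrow(), ntree = forest.size();
  IntegerMatrix votes(n, K);
  for (int b = 0; b < ntree; ++b) {
    List tr = forest[b];
    IntegerVector feat = tr["feat"], left = tr["left"], right = tr["right"], pred = tr["pred"];
    NumericVector thresh = tr["thresh"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thresh[node]) ? left[node] : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;
}
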