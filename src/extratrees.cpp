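// Extremely randomized trees (single- and multi-output binary classification).
//
// Each tree is grown by drawing, at every internal node, K candidate features
// (without replacement, among features non-constant within the node), one
// uniform random cut-point per candidate, and keeping the candidate with the
// largest Gini impurity decrease (summed over outputs).  Leaves store the
// class-1 frequency per output.  Trees are returned to R as flat parallel
// vectors so that fitted models are plain, serialisable R lists and the tree
// structure stays inspectable (bicluster extraction walks these vectors).
//
// Determinism: a single xorshift-free mt19937_64 stream seeded from R drives
// all randomness; uniform draws avoid std::*_distribution so results are
// reproducible across standard libraries.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform double in [0, 1)
  double unif() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(unif() * n); }
};

struct TreeBuf {
  std::vector<int> feature;      // split feature, -1 for leaf
  std::vector<double> threshold; // go left iff x[feature] <= threshold
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<int> n_node;       // training samples reaching the node
  std::vector<double> prob;      // n_nodes x n_outputs, row-major
};

struct StackItem {
  int node_id;
  int begin, end; // range into idx
};

inline double gini_sum(const std::vector<double> &cnt1, int n, int q) {
  double g = 0.0;
  for (int k = 0; k < q; ++k) {
    double p = cnt1[k] / n;
    g += 2.0 * p * (1.0 - p);
  }
  return g;
}

} // namespace

// [[Rcpp::export(name = ".et_fit_cpp")]]
List et_fit_cpp(NumericMatrix X, NumericMatrix Y, int n_trees, int k_features,
                bool bootstrap, int min_samples_split, double smoothing,
                double seed) {
  const int n = X.nrow(), p = X.ncol(), q = Y.ncol();
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  if (n < 1) stop("at least one training sample is required");
  if (k_features < 1 || k_features > p) stop("k_features out of range");

  Rng rng(static_cast<uint64_t>(seed));
  const double *xp = X.begin();
  const double *yp = Y.begin();

  std::vector<double> importance(p, 0.0);
  List trees(n_trees);

  std::vector<int> idx(n), feat_pool(p);
  std::vector<double> cnt(q), cntL(q), best_cntL(q);
  std::vector<double> xbuf(n), ybuf(q == 1 ? n : 0);

  for (int t = 0; t < n_trees; ++t) {
    if (bootstrap) {
      for (int i = 0; i < n; ++i) idx[i] = rng.unif_int(n);
    } else {
      for (int i = 0; i < n; ++i) idx[i] = i;
    }

    TreeBuf tb;
    std::vector<StackItem> stack;
    auto new_node = [&](int nn) {
      tb.feature.push_back(-1);
      tb.threshold.push_back(0.0);
      tb.left.push_back(-1);
      tb.right.push_back(-1);
      tb.n_node.push_back(nn);
      tb.prob.resize(tb.prob.size() + q, 0.0);
      return static_cast<int>(tb.feature.size()) - 1;
    };

    int root = new_node(n);
    stack.push_back({root, 0, n});

    while (!stack.empty()) {
      StackItem it = stack.back();
      stack.pop_back();
      const int nb = it.end - it.begin;

      // per-output class-1 counts
      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int i = it.begin; i < it.end; ++i) {
        const double *yrow = yp + idx[i];
        for (int k = 0; k < q; ++k) cnt[k] += yrow[(size_t)k * n];
      }
      double *pr = &tb.prob[(size_t)it.node_id * q];
      for (int k = 0; k < q; ++k)
        pr[k] = (cnt[k] + smoothing) / (nb + 2.0 * smoothing);

      bool pure = true;
      for (int k = 0; k < q && pure; ++k)
        if (cnt[k] > 0.0 && cnt[k] < nb) pure = false;
      if (pure || nb < min_samples_split) continue; // leaf

      // draw up to K valid candidate splits (features non-constant in node)
      double g_parent = gini_sum(cnt, nb, q);
      int best_f = -1;
      double best_thr = 0.0, best_score = -1.0;
      int best_nL = 0;

      if (q == 1) { // contiguous label buffer for the single-output hot path
        for (int i = it.begin; i < it.end; ++i)
          ybuf[i - it.begin] = yp[idx[i]];
      }

      for (int f0 = 0; f0 < p; ++f0) feat_pool[f0] = f0;
      int pool_sz = p, tried_valid = 0;
      while (pool_sz > 0 && tried_valid < k_features) {
        int j = rng.unif_int(pool_sz);
        int f = feat_pool[j];
        feat_pool[j] = feat_pool[--pool_sz];

        const double *xf = xp + (size_t)f * n;
        double mn = xf[idx[it.begin]], mx = mn;
        xbuf[0] = mn;
        for (int i = it.begin + 1; i < it.end; ++i) {
          double v = xf[idx[i]];
          xbuf[i - it.begin] = v;
          if (v < mn) mn = v;
          else if (v > mx) mx = v;
        }
        if (mx <= mn) continue; // constant here: not a candidate
        ++tried_valid;

        double thr = mn + rng.unif() * (mx - mn); // in [mn, mx)
        int nL = 0;
        if (q == 1) {
          double c1 = 0.0;
          for (int i = 0; i < nb; ++i) {
            if (xbuf[i] <= thr) {
              ++nL;
              c1 += ybuf[i];
            }
          }
          cntL[0] = c1;
        } else {
          std::fill(cntL.begin(), cntL.end(), 0.0);
          for (int i = it.begin; i < it.end; ++i) {
            if (xbuf[i - it.begin] <= thr) {
              ++nL;
              const double *yrow = yp + idx[i];
              for (int k = 0; k < q; ++k) cntL[k] += yrow[(size_t)k * n];
            }
          }
        }
        int nR = nb - nL;
        if (nL == 0 || nR == 0) continue; // cannot happen with thr in [mn,mx) but guard

        double gL = 0.0, gR = 0.0;
        for (int k = 0; k < q; ++k) {
          double pL = cntL[k] / nL, pR = (cnt[k] - cntL[k]) / nR;
          gL += 2.0 * pL * (1.0 - pL);
          gR += 2.0 * pR * (1.0 - pR);
        }
        double score = nb * g_parent - (nL * gL + nR * gR);
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = thr;
          best_nL = nL;
          best_cntL = cntL;
        }
      }

      if (best_f < 0) continue; // all features constant in node: leaf

      // partition idx[begin:end) in place on the chosen split
      const double *xf = xp + (size_t)best_f * n;
      int i = it.begin, j2 = it.end - 1;
      while (i <= j2) {
        if (xf[idx[i]] <= best_thr) {
          ++i;
        } else {
          std::swap(idx[i], idx[j2]);
          --j2;
        }
      }
      // i == begin + nL
      tb.feature[it.node_id] = best_f;
      tb.threshold[it.node_id] = best_thr;
      importance[best_f] += best_score; // total impurity decrease

      int lid = new_node(best_nL);
      int rid = new_node(nb - best_nL);
      tb.left[it.node_id] = lid;
      tb.right[it.node_id] = rid;
      stack.push_back({rid, it.begin + best_nL, it.end});
      stack.push_back({lid, it.begin, it.begin + best_nL});
    }

    int n_nodes = static_cast<int>(tb.feature.size());
    NumericMatrix prob(n_nodes, q);
    for (int nd = 0; nd < n_nodes; ++nd)
      for (int k = 0; k < q; ++k) prob(nd, k) = tb.prob[(size_t)nd * q + k];

    trees[t] = List::create(
        _["feature"] = IntegerVector(tb.feature.begin(), tb.feature.end()),
        _["threshold"] = NumericVector(tb.threshold.begin(), tb.threshold.end()),
        _["left"] = IntegerVector(tb.left.begin(), tb.left.end()),
        _["right"] = IntegerVector(tb.right.begin(), tb.right.end()),
        _["n_node"] = IntegerVector(tb.n_node.begin(), tb.n_node.end()),
        _["prob"] = prob);
  }

  return List::create(_["trees"] = trees,
                      _["importance_raw"] = NumericVector(importance.begin(), importance.end()),
                      _["n_features"] = p, _["n_outputs"] = q);
}

// [[Rcpp::export(name = ".et_predict_cpp")]]
NumericMatrix et_predict_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int p = as<int>(forest["n_features"]);
  const int q = as<int>(forest["n_outputs"]);
  const int n = X.nrow(), n_trees = trees.size();
  if (X.ncol() != p) stop("feature count mismatch: model expects %d, got %d", p, X.ncol());

  NumericMatrix out(n, q);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"];
    NumericMatrix prob = tr["prob"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0)
        nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
      for (int k = 0; k < q; ++k) out(i, k) += prob(nd, k);
    }
  }
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < q; ++k) out(i, k) /= n_trees;
  return out;
}

// [[Rcpp::export(name = ".et_leaf_cpp")]]
IntegerMatrix et_leaf_cpp(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int p = as<int>(forest["n_features"]);
  const int n = X.nrow(), n_trees = trees.size();
  if (X.ncol() != p) stop("feature count mismatch: model expects %d, got %d", p, X.ncol());

  IntegerMatrix out(n, n_trees);
  for (int t = 0; t < n_trees; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"], right = tr["right"];
    NumericVector threshold = tr["threshold"];
    for (int i = 0; i < n; ++i) {
      int nd = 0;
      while (feature[nd] >= 0)
        nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
      out(i, t) = nd; // 0-based node id within the tree
    }
  }
  return out;
}
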