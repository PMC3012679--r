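#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Regression CART / random-forest internals.
//
// Tree encoding: one NumericMatrix per tree, one row per node, columns
//   0 var   split predictor (0-based; -1 for a leaf)
//   1 thr   split threshold (x <= thr goes left)
//   2 left  row index of left child
//   3 right row index of right child
//   4 value leaf mean (response units); NA on internal nodes
//
// All randomness (predictor subsets, permutations) comes from R's RNG so a
// single set.seed() on the R side fixes the whole fit bit-for-bit.

static inline double predict_one(const NumericMatrix& tr, const double* xrow) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    int j = (int) tr(node, 0);
    node = (xrow[j] <= tr(node, 1)) ? (int) tr(node, 2) : (int) tr(node, 3);
  }
  return tr(node, 4);
}

// predict with one predictor's value overridden (for permutation importance)
static inline double predict_one_override(const NumericMatrix& tr, const double* xrow,
                                          int jover, double xval) {
  int node = 0;
  while (tr(node, 0) >= 0) {
    int j = (int) tr(node, 0);
    double x = (j == jover) ? xval : xrow[j];
    node = (x <= tr(node, 1)) ? (int) tr(node, 2) : (int) tr(node, 3);
  }
  return tr(node, 4);
}

// draw `m` distinct integers from 0..(p-1) via partial Fisher-Yates (R RNG),
// returned sorted ascending so ties in split score resolve to the lowest
// predictor index
static void sample_predictors(std::vector<int>& pool, int m, std::vector<int>& out) {
  int p = (int) pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + (int) (unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
  }
  out.assign(pool.begin(), pool.begin() + m);
  std::sort(out.begin(), out.end());
}

struct Builder {
  const NumericMatrix& X;
  const std::vector<double>& y;   // responses for the in-bag multiset
  const std::vector<int>& rows;   // X row (0-based) for each in-bag sample
  int mtry, min_leaf;
  std::vector<double> var_, thr_, val_;
  std::vector<int> left_, right_;
  std::vector<int> idx;           // permutation of 0..(nb-1), partitioned in place
  std::vector<int> pool;          // predictor pool for subsampling
  std::vector<int> cand;
  std::vector<std::pair<double, int> > buf;

  Builder(const NumericMatrix& X_, const std::vector<double>& y_,
          const std::vector<int>& rows_, int mtry_, int min_leaf_)
    : X(X_), y(y_), rows(rows_), mtry(mtry_), min_leaf(min_leaf_) {
    idx.resize(y.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int) i;
    pool.resize(X.ncol());
    for (int j = 0; j < X.ncol(); ++j) pool[j] = j;
  }

  int new_node() {
    var_.push_back(-1); thr_.push_back(NA_REAL); val_.push_back(NA_REAL);
    left_.push_back(-1); right_.push_back(-1);
    return (int) var_.size() - 1;
  }

  // grow node from idx[start, end); returns node row
  int grow(int start, int end) {
    int node = new_node();
    int n = end - start;
    double sum = 0.0, sum2 = 0.0;
    for (int i = start; i < end; ++i) { double v = y[idx[i]]; sum += v; sum2 += v * v; }
    double mean = sum / n;
    val_[node] = mean;
    double ss = sum2 - sum * sum / n;
    if (n < 2 * min_leaf || ss <= 0.0) return node;  // too small or constant

    // best split over a fresh random predictor subset
    double base = sum * sum / n;
    double best_score = base;            // require strict improvement
    int best_var = -1;
    double best_thr = 0.0;
    sample_predictors(pool, mtry, cand);
    for (size_t c = 0; c < cand.size(); ++c) {
      int j = cand[c];
      buf.clear();
      for (int i = start; i < end; ++i)
        buf.push_back(std::make_pair(X(rows[idx[i]], j), idx[i]));
      std::sort(buf.begin(), buf.end());
      double sl = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        sl += y[buf[i].second];
        int nl = i + 1, nr = n - nl;
        if (nl < min_leaf) continue;
        if (nr < min_leaf) break;
        if (buf[i].first == buf[i + 1].first) continue;  // not a boundary
        double sr = sum - sl;
        double score = sl * sl / nl + sr * sr / nr;
        if (score > best_score + 1e-10 * std::abs(base)) {
          best_score = score;
          best_var = j;
          best_thr = buf[i].first + (buf[i + 1].first - buf[i].first) / 2.0;
        }
      }
    }
    if (best_var < 0) return node;  // no admissible split improves SSE

    // partition idx[start,end) on the chosen split
    int lo = start, hi = end - 1;
    while (lo <= hi) {
      if (X(rows[idx[lo]], best_var) <= best_thr) { ++lo; }
      else { std::swap(idx[lo], idx[hi]); --hi; }
    }
    // degenerate guard (should not happen with boundary thresholds)
    if (lo == start || lo == end) return node;
    var_[node] = best_var;
    thr_[node] = best_thr;
    val_[node] = NA_REAL;
    int l = grow(start, lo);
    int r = grow(lo, end);
    left_[node] = l;
    right_[node] = r;
    return node;
  }

  NumericMatrix as_matrix() {
    int m = (int) var_.size();
    NumericMatrix out(m, 5);
    for (int i = 0; i < m; ++i) {
      out(i, 0) = var_[i]; out(i, 1) = thr_[i];
      out(i, 2) = left_[i]; out(i, 3) = right_[i];
      out(i, 4) = val_[i];
    }
    return out;
  }
};

// [[Rcpp::export]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, List inbag, int mtry, int min_leaf) {
  int ntree = inbag.size();
  List trees(ntree);
  for (int t = 0; t < ntree; ++t) {
    IntegerVector bag = inbag[t];  // 1-based row indices, with multiplicity
    int nb = bag.size();
    std::vector<double> yb(nb);
    std::vector<int> rows(nb);
    for (int i = 0; i < nb; ++i) { rows[i] = bag[i] - 1; yb[i] = y[rows[i]]; }
    Builder b(X, yb, rows, mtry, min_leaf);
    b.grow(0, nb);
    trees[t] = b.as_matrix();
  }
  return trees;
}

// [[Rcpp::export]]
NumericVector rf_predict_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size(), p = X.ncol();
  NumericVector out(n);
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    bool miss = false;
    for (int j = 0; j < p; ++j) if (NumericVector::is_na(xrow[j])) { miss = true; break; }
    if (miss) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int t = 0; t < ntree; ++t) s += predict_one(trees[t], &xrow[0]);
    out[i] = s / ntree;
  }
  return out;
}

// OOB predictions: sample i averages only the trees where inbag_count[i, t] == 0
// [[Rcpp::export]]
List rf_oob_cpp(List trees, NumericMatrix X, IntegerMatrix inbag_count) {
  int n = X.nrow(), ntree = trees.size(), p = X.ncol();
  NumericVector pred(n);
  IntegerVector cnt(n);
  std::vector<double> xrow(p);
  for (int i = 0; i < n; ++i) {
    double s = 0.0; int m = 0;
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    for (int t = 0; t < ntree; ++t) {
      if (inbag_count(i, t) == 0) {
        s += predict_one(trees[t], &xrow[0]);
        ++m;
      }
    }
    cnt[i] = m;
    pred[i] = (m > 0) ? s / m : NA_REAL;
  }
  return List::create(_["pred"] = pred, _["n_oob_trees"] = cnt);
}

// Per-tree accuracy importance: increase of the tree's OOB MSE after permuting
// one predictor among that tree's OOB samples. Returns p x ntree matrix.
// [[Rcpp::export]]
NumericMatrix rf_perm_importance_cpp(List trees, NumericMatrix X, NumericVector y,
                                     IntegerMatrix inbag_count, int nrep) {
  int n = X.nrow(), p = X.ncol(), ntree = trees.size();
  NumericMatrix out(p, ntree);
  std::vector<int> oob;
  std::vector<double> xperm, xrow(p);
  for (int t = 0; t < ntree; ++t) {
    const NumericMatrix tr = trees[t];
    oob.clear();
    for (int i = 0; i < n; ++i) if (inbag_count(i, t) == 0) oob.push_back(i);
    int m = (int) oob.size();
    if (m == 0) { for (int j = 0; j < p; ++j) out(j, t) = NA_REAL; continue; }
    double err0 = 0.0;
    for (int k = 0; k < m; ++k) {
      int i = oob[k];
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      double d = predict_one(tr, &xrow[0]) - y[i];
      err0 += d * d;
    }
    err0 /= m;
    for (int j = 0; j < p; ++j) {
      double inc = 0.0;
      for (int r = 0; r < nrep; ++r) {
        xperm.resize(m);
        for (int k = 0; k < m; ++k) xperm[k] = X(oob[k], j);
        for (int k = m - 1; k > 0; --k) {  // Fisher-Yates with R RNG
          int q = (int) (unif_rand() * (k + 1));
          if (q > k) q = k;
          std::swap(xperm[k], xperm[q]);
        }
        double err = 0.0;
        for (int k = 0; k < m; ++k) {
          int i = oob[k];
          for (int jj = 0; jj < p; ++jj) xrow[jj] = X(i, jj);
          double d = predict_one_override(tr, &xrow[0], j, xperm[k]) - y[i];
          err += d * d;
        }
        err /= m;
        inc += err - err0;
      }
      out(j, t) = inc / nrep;
    }
  }
  return out;
}
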