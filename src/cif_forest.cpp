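// Conditional-inference trees and forests for a binary phenotype.
//
// Split-variable selection is a hypothesis-testing procedure, separated from
// split-point selection: at each node a permutation-form linear statistic
// T = sum_i x_i y_i is standardized by its conditional mean and variance and
// referred to the normal distribution; the global null (no candidate is
// associated with the response) is rejected only if the minimal
// Bonferroni-adjusted p-value falls below alpha. The split point then
// maximizes the standardized two-sample statistic over observed values.
//
// All randomness flows through R's RNG so set.seed() governs everything.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> var;       // split column (0-based), -1 for leaf
  std::vector<double> split;  // go left iff x <= split
  std::vector<int> left, right;
  std::vector<double> pred;   // class-1 fraction in the node
  std::vector<int> nn;        // node size (bootstrap weights included)
};

// standardized linear statistic and normal p-value for x (rows idx) vs y
double linear_stat_p(const NumericMatrix& X, const IntegerVector& y,
                     const std::vector<int>& idx, int col,
                     bool& constant, double& zabs) {
  const int n = (int)idx.size();
  double sx = 0.0, sy = 0.0, t = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xv = X(idx[i], col);
    sx += xv;
    sy += y[idx[i]];
    t += xv * y[idx[i]];
  }
  const double mx = sx / n;
  double vx = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = X(idx[i], col) - mx;
    vx += d * d;
  }
  const double vy = sy - sy * sy / n;  // y binary: sum y^2 == sum y
  constant = (vx <= 1e-12 * std::max(1.0, mx * mx * n));
  if (constant || vy <= 0.0) { zabs = 0.0; return 1.0; }
  const double e = sx * sy / n;
  const double sigma = std::sqrt(vx * vy / (n - 1));
  zabs = std::fabs(t - e) / sigma;
  return 2.0 * R::pnorm(-zabs, 0.0, 1.0, 1, 0);
}

// Monte-Carlo permutation p-value for the same statistic
double perm_stat_p(const NumericMatrix& X, const IntegerVector& y,
                   const std::vector<int>& idx, int col, int n_perm) {
  const int n = (int)idx.size();
  std::vector<double> xv(n);
  std::vector<int> yv(n);
  double sx = 0.0, sy = 0.0, t = 0.0;
  for (int i = 0; i < n; ++i) {
    xv[i] = X(idx[i], col);
    yv[i] = y[idx[i]];
    sx += xv[i]; sy += yv[i]; t += xv[i] * yv[i];
  }
  const double e = sx * sy / n;
  const double tobs = std::fabs(t - e);
  int count = 0;
  std::vector<int> yp(yv);
  for (int b = 0; b < n_perm; ++b) {
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      std::swap(yp[i], yp[j]);
    }
    double tp = 0.0;
    for (int i = 0; i < n; ++i) tp += xv[i] * yp[i];
    if (std::fabs(tp - e) >= tobs - 1e-12) ++count;
  }
  return (count + 1.0) / (n_perm + 1.0);
}

struct Builder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int mtry, min_node;
  double alpha;
  bool montecarlo;
  int n_perm_split;
  Tree tree;
  std::vector<int> varpool;

  Builder(const NumericMatrix& X_, const IntegerVector& y_, int mtry_,
          int min_node_, double alpha_, bool mc_, int nps_)
      : X(X_), y(y_), mtry(mtry_), min_node(min_node_), alpha(alpha_),
        montecarlo(mc_), n_perm_split(nps_), varpool(X_.ncol()) {
    for (int j = 0; j < X.ncol(); ++j) varpool[j] = j;
  }

  int make_leaf(double frac, int n) {
    tree.var.push_back(-1);
    tree.split.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(frac);
    tree.nn.push_back(n);
    return (int)tree.var.size() - 1;
  }

  int build(std::vector<int>& idx) {
    const int n = (int)idx.size();
    double sy = 0.0;
    for (int i = 0; i < n; ++i) sy += y[idx[i]];
    const double frac = sy / n;
    if (n < 2 * min_node || sy == 0.0 || sy == n) return make_leaf(frac, n);

    // draw mtry candidate variables (partial Fisher-Yates, R RNG)
    const int p = (int)varpool.size();
    const int m = std::min(mtry, p);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(unif_rand() * (p - i));
      std::swap(varpool[i], varpool[j]);
    }

    int best_col = -1, n_valid = 0;
    double best_p = 2.0;
    for (int i = 0; i < m; ++i) {
      bool constant; double zabs;
      double pv = linear_stat_p(X, y, idx, varpool[i], constant, zabs);
      if (constant) continue;
      ++n_valid;
      if (montecarlo)
        pv = perm_stat_p(X, y, idx, varpool[i], n_perm_split);
      if (pv < best_p) { best_p = pv; best_col = varpool[i]; }
    }
    if (best_col < 0) return make_leaf(frac, n);
    const double p_adj = std::min(1.0, best_p * n_valid);
    if (p_adj >= alpha) return make_leaf(frac, n);  // global null retained

    // split point: maximize the standardized two-sample statistic over
    // observed values of the selected variable
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      return X(a, best_col) < X(b, best_col);
    });
    const double vy = sy - sy * sy / n;
    double best_z = -1.0;
    int best_k = -1;
    double cumy = 0.0;
    for (int k = 1; k < n; ++k) {  // k = size of left child
      cumy += y[idx[k - 1]];
      if (k < min_node || n - k < min_node) continue;
      if (X(idx[k - 1], best_col) >= X(idx[k], best_col)) continue;  // tie
      const double e = (double)k * sy / n;
      const double vg = k - (double)k * k / n;
      const double z = std::fabs(cumy - e) / std::sqrt(vg * vy / (n - 1));
      if (z > best_z + 1e-12) { best_z = z; best_k = k; }
    }
    if (best_k < 0) return make_leaf(frac, n);
    const double cut = X(idx[best_k - 1], best_col);

    std::vector<int> lidx(idx.begin(), idx.begin() + best_k);
    std::vector<int> ridx(idx.begin() + best_k, idx.end());
    const int self = make_leaf(frac, n);  // placeholder, turned internal below
    tree.var[self] = best_col;
    tree.split[self] = cut;
    const int l = build(lidx);
    const int r = build(ridx);
    tree.left[self] = l;
    tree.right[self] = r;
    return self;
  }
};

double route(const Tree& t, const NumericMatrix& X, int row) {
  int cur = 0;
  while (t.var[cur] >= 0) {
    cur = (X(row, t.var[cur]) <= t.split[cur]) ? t.left[cur] : t.right[cur];
  }
  return t.pred[cur];
}

double route_swap(const Tree& t, const NumericMatrix& X, int row,
                  int swap_col, int swap_row) {
  int cur = 0;
  while (t.var[cur] >= 0) {
    const int col = t.var[cur];
    const double v = (col == swap_col) ? X(swap_row, col) : X(row, col);
    cur = (v <= t.split[cur]) ? t.left[cur] : t.right[cur];
  }
  return t.pred[cur];
}

Tree tree_from_list(const List& tl) {
  Tree t;
  t.var = as<std::vector<int>>(tl["var"]);
  t.split = as<std::vector<double>>(tl["split"]);
  t.left = as<std::vector<int>>(tl["left"]);
  t.right = as<std::vector<int>>(tl["right"]);
  t.pred = as<std::vector<double>>(tl["pred"]);
  return t;
}

}  // namespace

// bootstrap_mode: 0 = size-n resample with replacement, 1 = 0.632n
// subsample without replacement, 2 = none (every tree sees the full sample)
// [[Rcpp::export]]
List cpp_build_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                      double alpha, int min_node, int bootstrap_mode,
                      bool montecarlo, int n_perm_split) {
  const int n = X.nrow();
  List trees(ntree), oob_list(ntree);
  std::vector<int> inbag(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx;
    if (bootstrap_mode == 2) {
      idx.resize(n);
      for (int i = 0; i < n; ++i) { idx[i] = i; inbag[i] = 1; }
    } else if (bootstrap_mode == 0) {
      idx.reserve(n);
      for (int i = 0; i < n; ++i) {
        int j = (int)(unif_rand() * n);
        idx.push_back(j);
        inbag[j] = 1;
      }
    } else {
      const int k = (int)std::floor(0.632 * n);
      std::vector<int> perm(n);
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = 0; i < k; ++i) {
        int j = i + (int)(unif_rand() * (n - i));
        std::swap(perm[i], perm[j]);
      }
      idx.assign(perm.begin(), perm.begin() + k);
      for (int i = 0; i < k; ++i) inbag[idx[i]] = 1;
    }
    Builder b(X, y, mtry, min_node, alpha, montecarlo, n_perm_split);
    b.build(idx);
    IntegerVector oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i + 1);
    trees[t] = List::create(
        _["var"] = wrap(b.tree.var), _["split"] = wrap(b.tree.split),
        _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
        _["pred"] = wrap(b.tree.pred), _["n"] = wrap(b.tree.nn));
    oob_list[t] = oob;
  }
  return List::create(_["trees"] = trees, _["oob"] = oob_list);
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    for (int i = 0; i < n; ++i) out[i] += route(tr, X, i);
  }
  return out / (double)ntree;
}

// [[Rcpp::export]]
List cpp_oob_predict(List trees, List oob, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector sum(n);
  IntegerVector cnt(n);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    IntegerVector o = oob[t];
    for (int k = 0; k < o.size(); ++k) {
      const int i = o[k] - 1;
      sum[i] += route(tr, X, i);
      cnt[i] += 1;
    }
  }
  return List::create(_["sum"] = sum, _["count"] = cnt);
}

// [[Rcpp::export]]
NumericVector cpp_permutation_importance(List trees, List oob,
                                         NumericMatrix X, IntegerVector y) {
  const int p = X.ncol(), ntree = trees.size();
  NumericVector imp(p);
  std::vector<int> used(p);
  for (int t = 0; t < ntree; ++t) {
    Tree tr = tree_from_list(trees[t]);
    IntegerVector o = oob[t];
    const int m = o.size();
    if (m == 0) continue;
    std::fill(used.begin(), used.end(), 0);
    for (size_t k = 0; k < tr.var.size(); ++k)
      if (tr.var[k] >= 0) used[tr.var[k]] = 1;
    // baseline OOB accuracy at the 0.5 probability cut
    int correct = 0;
    for (int k = 0; k < m; ++k) {
      const int i = o[k] - 1;
      const int cls = route(tr, X, i) > 0.5 ? 1 : 0;
      if (cls == y[i]) ++correct;
    }
    const double acc = (double)correct / m;
    std::vector<int> perm(m);
    for (int v = 0; v < p; ++v) {
      if (!used[v]) continue;  // unused variable: importance contribution 0
      for (int k = 0; k < m; ++k) perm[k] = o[k] - 1;
      for (int k = m - 1; k > 0; --k) {
        int j = (int)(unif_rand() * (k + 1));
        std::swap(perm[k], perm[j]);
      }
      int corr_p = 0;
      for (int k = 0; k < m; ++k) {
        const int i = o[k] - 1;
        const int cls = route_swap(tr, X, i, v, perm[k]) > 0.5 ? 1 : 0;
        if (cls == y[i]) ++corr_p;
      }
      imp[v] += acc - (double)corr_p / m;
    }
  }
  return imp / (double)ntree;
}

// Screening-tool evaluation: confusion counts for a batch of random
// threshold tools on one variable subset. Z is n x k (standardized members),
// L and U are R x k threshold matrices. The any-out-of-bounds rule
// short-circuits per patient.
// [[Rcpp::export]]
List cpp_eval_tools(NumericMatrix Z, IntegerVector y, NumericMatrix L,
                    NumericMatrix U) {
  const int n = Z.nrow(), k = Z.ncol(), R = L.nrow();
  IntegerVector tp(R), pp(R);
  for (int r = 0; r < R; ++r) {
    int tpr_ = 0, ppr = 0;
    for (int i = 0; i < n; ++i) {
      bool flag = false;
      for (int j = 0; j < k; ++j) {
        const double z = Z(i, j);
        if (z > U(r, j) || z < L(r, j)) { flag = true; break; }
      }
      if (flag) {
        ++ppr;
        if (y[i] == 1) ++tpr_;
      }
    }
    tp[r] = tpr_;
    pp[r] = ppr;
  }
  return List::create(_["tp"] = tp, _["pp"] = pp);
}
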