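// Exact tree-path-dependent Shapley values (and Shapley interaction values)
// for shallow binary-tree ensembles, by per-leaf coalition enumeration.
//
// For a single leaf L, the conditional expectation E[f | x_S] contributes
// g_L(S) * value_L, where g_L(S) factorises over the distinct features on the
// root->leaf path: features in S contribute an indicator (does x satisfy every
// split on that feature along the path), features not in S contribute the
// product of training cover ratios of their edges. With tree depth d the
// coalition sum runs over at most 2^d subsets, so enumeration is exact and
// cheap for the shallow forests used here (max depth <= 6). Intended for
// shallow trees; depth is guarded at 20 distinct features per path.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct LeafPath {
  double value;                    // leaf prediction (probability of class 1)
  std::vector<int> feats;          // distinct 0-based feature ids on path
  std::vector<double> covw;        // per distinct feature: product of cover ratios
  // per distinct feature: split constraints (threshold, go_left)
  std::vector<std::vector<std::pair<double, int>>> constr;
};

static void collect_leaves(int node, const IntegerVector& left, const IntegerVector& right,
                           const IntegerVector& feature, const NumericVector& threshold,
                           const NumericVector& value, const NumericVector& cover,
                           std::vector<int>& pf, std::vector<double>& pw,
                           std::vector<std::pair<double, int>>& pc_thr,
                           std::vector<LeafPath>& leaves) {
  if (feature[node] < 0) {
    LeafPath lp;
    lp.value = value[node];
    // aggregate by distinct feature
    for (size_t i = 0; i < pf.size(); ++i) {
      int f = pf[i];
      int k = -1;
      for (size_t j = 0; j < lp.feats.size(); ++j)
        if (lp.feats[j] == f) { k = (int)j; break; }
      if (k < 0) {
        lp.feats.push_back(f);
        lp.covw.push_back(1.0);
        lp.constr.push_back({});
        k = (int)lp.feats.size() - 1;
      }
      lp.covw[k] *= pw[i];
      lp.constr[k].push_back(pc_thr[i]);
    }
    if (lp.feats.size() > 20) stop("tree path has more than 20 distinct features");
    leaves.push_back(lp);
    return;
  }
  int f = feature[node];
  double cn = cover[node];
  int l = left[node], r = right[node];
  double wl = cn > 0 ? cover[l] / cn : 0.5;
  double wr = cn > 0 ? cover[r] / cn : 0.5;
  pf.push_back(f); pw.push_back(wl); pc_thr.push_back({threshold[node], 1});
  collect_leaves(l, left, right, feature, threshold, value, cover, pf, pw, pc_thr, leaves);
  pf.pop_back(); pw.pop_back(); pc_thr.pop_back();
  pf.push_back(f); pw.push_back(wr); pc_thr.push_back({threshold[node], 0});
  collect_leaves(r, left, right, feature, threshold, value, cover, pf, pw, pc_thr, leaves);
  pf.pop_back(); pw.pop_back(); pc_thr.pop_back();
}

static std::vector<LeafPath> tree_leaves(const List& tree) {
  IntegerVector left = tree["left"], right = tree["right"], feature = tree["feature"];
  NumericVector threshold = tree["threshold"], value = tree["value"], cover = tree["cover"];
  std::vector<LeafPath> leaves;
  std::vector<int> pf;
  std::vector<double> pw;
  std::vector<std::pair<double, int>> pc;
  collect_leaves(0, left, right, feature, threshold, value, cover, pf, pw, pc, leaves);
  return leaves;
}

static const int MAXF = 24;
static double FACT[MAXF + 1];
static void init_fact() {
  FACT[0] = 1.0;
  for (int i = 1; i <= MAXF; ++i) FACT[i] = FACT[i - 1] * i;
}

// decision rule: x <= threshold goes left
static inline bool satisfies(double xv, const std::vector<std::pair<double, int>>& cs) {
  for (auto& c : cs) {
    bool goleft = xv <= c.first;
    if (goleft != (c.second == 1)) return false;
  }
  return true;
}

// Shapley contributions of one leaf for one sample, added into phi
static void leaf_phi(const LeafPath& lp, const NumericVector& x, double* phi, double& base) {
  int m = (int)lp.feats.size();
  if (m == 0) {
    base += lp.value;
    return;
  }
  std::vector<double> ind(m), cw(m);
  for (int i = 0; i < m; ++i) {
    ind[i] = satisfies(x[lp.feats[i]], lp.constr[i]) ? 1.0 : 0.0;
    cw[i] = lp.covw[i];
  }
  int nm = 1 << m;
  std::vector<double> g(nm);
  for (int mask = 0; mask < nm; ++mask) {
    double p = 1.0;
    for (int i = 0; i < m; ++i) p *= (mask & (1 << i)) ? ind[i] : cw[i];
    g[mask] = p;
  }
  base += g[0] * lp.value;
  for (int i = 0; i < m; ++i) {
    double acc = 0.0;
    for (int mask = 0; mask < nm; ++mask) {
      if (mask & (1 << i)) continue;
      int s = __builtin_popcount(mask);
      double w = FACT[s] * FACT[m - s - 1] / FACT[m];
      acc += w * (g[mask | (1 << i)] - g[mask]);
    }
    phi[lp.feats[i]] += acc * lp.value;
  }
}

// [[Rcpp::export]]
List forest_shap_cpp(List forest, NumericMatrix X, int n_features) {
  init_fact();
  int n = X.nrow(), nt = forest.size();
  NumericMatrix phi(n, n_features);
  double base = 0.0;
  std::vector<std::vector<LeafPath>> all_leaves(nt);
  for (int t = 0; t < nt; ++t) all_leaves[t] = tree_leaves(forest[t]);
  std::vector<double> phirow(n_features);
  for (int i = 0; i < n; ++i) {
    NumericVector x = X(i, _);
    std::fill(phirow.begin(), phirow.end(), 0.0);
    double b = 0.0;
    for (int t = 0; t < nt; ++t)
      for (const LeafPath& lp : all_leaves[t]) leaf_phi(lp, x, phirow.data(), b);
    if (i == 0) base = b;  // identical for every sample
    for (int j = 0; j < n_features; ++j) phi(i, j) = phirow[j] / nt;
  }
  return List::create(_["phi"] = phi, _["base"] = base / nt);
}

// Dense symmetric Shapley interaction matrix for a single sample.
// Off-diagonal cells carry half the pairwise interaction index; diagonal is
// phi_i minus the off-diagonal row sum, so the full matrix sums to f(x) - base.
// [[Rcpp::export]]
NumericMatrix forest_shap_interactions_cpp(List forest, NumericVector x, int n_features) {
  init_fact();
  int nt = forest.size();
  NumericMatrix I(n_features, n_features);
  std::vector<double> phi(n_features, 0.0);
  double base = 0.0;
  for (int t = 0; t < nt; ++t) {
    std::vector<LeafPath> leaves = tree_leaves(forest[t]);
    for (const LeafPath& lp : leaves) {
      int m = (int)lp.feats.size();
      leaf_phi(lp, x, phi.data(), base);
      if (m < 2) continue;
      std::vector<double> ind(m), cw(m);
      for (int i = 0; i < m; ++i) {
        ind[i] = satisfies(x[lp.feats[i]], lp.constr[i]) ? 1.0 : 0.0;
        cw[i] = lp.covw[i];
      }
      int nm = 1 << m;
      std::vector<double> g(nm);
      for (int mask = 0; mask < nm; ++mask) {
        double p = 1.0;
        for (int i = 0; i < m; ++i) p *= (mask & (1 << i)) ? ind[i] : cw[i];
        g[mask] = p;
      }
      for (int a = 0; a < m; ++a) {
        for (int b = a + 1; b < m; ++b) {
          double acc = 0.0;
          int ba = 1 << a, bb = 1 << b;
          for (int mask = 0; mask < nm; ++mask) {
            if (mask & (ba | bb)) continue;
            int s = __builtin_popcount(mask);
            // |S|! (M-|S|-2)! / (2 (M-1)!)
            double w = FACT[s] * FACT[m - s - 2] / (2.0 * FACT[m - 1]);
            acc += w * (g[mask | ba | bb] - g[mask | ba] - g[mask | bb] + g[mask]);
          }
          double v = acc * lp.value;
          I(lp.feats[a], lp.feats[b]) += v;
          I(lp.feats[b], lp.feats[a]) += v;
        }
      }
    }
  }
  for (int i = 0; i < n_features; ++i) {
    double off = 0.0;
    for (int j = 0; j < n_features; ++j)
      if (j != i) {
        I(i, j) /= nt;
        off += I(i, j);
      }
    I(i, i) = phi[i] / nt - off;
  }
  I.attr("base") = base / nt;
  return I;
}

// Training-sample count reaching each node (x <= threshold goes left).
// [[Rcpp::export]]
NumericVector tree_cover_cpp(IntegerVector left, IntegerVector right, IntegerVector feature,
                             NumericVector threshold, NumericMatrix X) {
  int nn = left.size(), n = X.nrow();
  NumericVector cover(nn);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    for (;;) {
      cover[node] += 1.0;
      if (feature[node] < 0) break;
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
  }
  return cover;
}

// Per-sample leaf value of one tree (used to cross-check split semantics).
// [[Rcpp::export]]
NumericVector tree_predict_cpp(IntegerVector left, IntegerVector right, IntegerVector feature,
                               NumericVector threshold, NumericVector value, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0)
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    out[i] = value[node];
  }
  return out;
}
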