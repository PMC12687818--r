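// Exact path-dependent TreeSHAP for binary decision trees (Lundberg et al.
// polynomial-time algorithm), plus small numeric helpers. Trees arrive as
// parallel arrays (0-based child indices, -1 for none); the split rule is
// x[feature] <= threshold -> left child. Node "cover" is the number of
// training rows that reach the node, so cover(parent) = cover(left) +
// cover(right) and the SHAP efficiency property holds exactly.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct PathElement {
  int feature_index;
  double zero_fraction;
  double one_fraction;
  double pweight;
};

static void extend_path(PathElement *path, int unique_depth,
                        double zero_fraction, double one_fraction,
                        int feature_index) {
  path[unique_depth].feature_index = feature_index;
  path[unique_depth].zero_fraction = zero_fraction;
  path[unique_depth].one_fraction = one_fraction;
  path[unique_depth].pweight = unique_depth == 0 ? 1.0 : 0.0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    path[i + 1].pweight += one_fraction * path[i].pweight * (i + 1) /
      static_cast<double>(unique_depth + 1);
    path[i].pweight = zero_fraction * path[i].pweight * (unique_depth - i) /
      static_cast<double>(unique_depth + 1);
  }
}

static void unwind_path(PathElement *path, int unique_depth, int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = path[i].pweight;
      path[i].pweight = next_one_portion * (unique_depth + 1) /
        static_cast<double>((i + 1) * one_fraction);
      next_one_portion = tmp - path[i].pweight * zero_fraction *
        (unique_depth - i) / static_cast<double>(unique_depth + 1);
    } else {
      path[i].pweight = (path[i].pweight * (unique_depth + 1)) /
        (zero_fraction * (unique_depth - i));
    }
  }
  for (int i = path_index; i < unique_depth; ++i) {
    path[i].feature_index = path[i + 1].feature_index;
    path[i].zero_fraction = path[i + 1].zero_fraction;
    path[i].one_fraction = path[i + 1].one_fraction;
  }
}

static double unwound_path_sum(const PathElement *path, int unique_depth,
                               int path_index) {
  const double one_fraction = path[path_index].one_fraction;
  const double zero_fraction = path[path_index].zero_fraction;
  double next_one_portion = path[unique_depth].pweight;
  double total = 0;
  for (int i = unique_depth - 1; i >= 0; --i) {
    if (one_fraction != 0) {
      const double tmp = next_one_portion * (unique_depth + 1) /
        static_cast<double>((i + 1) * one_fraction);
      total += tmp;
      next_one_portion = path[i].pweight - tmp * zero_fraction *
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    } else {
      total += (path[i].pweight / zero_fraction) /
        ((unique_depth - i) / static_cast<double>(unique_depth + 1));
    }
  }
  return total;
}

struct Tree {
  const int *left, *right, *feature;
  const double *threshold, *value, *cover;
};

static void shap_recurse(const Tree &tr, const double *x, double *phi,
                         int node, int unique_depth,
                         PathElement *parent_path,
                         double parent_zero_fraction,
                         double parent_one_fraction,
                         int parent_feature_index) {
  PathElement *path = parent_path + unique_depth + 1;
  std::copy(parent_path, parent_path + unique_depth, path);
  extend_path(path, unique_depth, parent_zero_fraction, parent_one_fraction,
              parent_feature_index);
  if (tr.left[node] < 0) {  // leaf
    for (int i = 1; i <= unique_depth; ++i) {
      const double w = unwound_path_sum(path, unique_depth, i);
      phi[path[i].feature_index] +=
        w * (path[i].one_fraction - path[i].zero_fraction) * tr.value[node];
    }
    return;
  }
  const int f = tr.feature[node];
  const int hot = (x[f] <= tr.threshold[node]) ? tr.left[node] : tr.right[node];
  const int cold = (hot == tr.left[node]) ? tr.right[node] : tr.left[node];
  const double w = tr.cover[node];
  const double hot_zero = tr.cover[hot] / w;
  const double cold_zero = tr.cover[cold] / w;
  double incoming_zero = 1.0, incoming_one = 1.0;
  int path_index = 0;
  for (; path_index <= unique_depth; ++path_index)
    if (path[path_index].feature_index == f) break;
  if (path_index != unique_depth + 1) {
    incoming_zero = path[path_index].zero_fraction;
    incoming_one = path[path_index].one_fraction;
    unwind_path(path, unique_depth, path_index);
    unique_depth -= 1;
  }
  shap_recurse(tr, x, phi, hot, unique_depth + 1, path,
               hot_zero * incoming_zero, incoming_one, f);
  shap_recurse(tr, x, phi, cold, unique_depth + 1, path,
               cold_zero * incoming_zero, 0.0, f);
}

static int tree_depth(const Tree &tr, int node) {
  if (tr.left[node] < 0) return 1;
  return 1 + std::max(tree_depth(tr, tr.left[node]),
                      tree_depth(tr, tr.right[node]));
}

static Tree unpack_tree(const List &tree) {
  Tree tr;
  tr.left = INTEGER(tree["left"]);
  tr.right = INTEGER(tree["right"]);
  tr.feature = INTEGER(tree["feature"]);
  tr.threshold = REAL(tree["threshold"]);
  tr.value = REAL(tree["value"]);
  tr.cover = REAL(tree["cover"]);
  return tr;
}

// Count training rows reaching each node.
// [[Rcpp::export]]
NumericVector cpp_tree_cover(IntegerVector left, IntegerVector right,
                             IntegerVector feature, NumericVector threshold,
                             NumericMatrix X) {
  const int n = X.nrow();
  NumericVector cover(left.size());
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (true) {
      cover[node] += 1;
      if (left[node] < 0) break;
      node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                      : right[node];
    }
  }
  return cover;
}

// Mean leaf value over trees for each row (the forest's probability margin).
// [[Rcpp::export]]
NumericVector cpp_forest_margin(List trees, NumericMatrix X) {
  const int n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < trees.size(); ++t) {
    const List tree = trees[t];
    const Tree tr = unpack_tree(tree);
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (tr.left[node] >= 0)
        node = (X(i, tr.feature[node]) <= tr.threshold[node]) ? tr.left[node]
                                                              : tr.right[node];
      out[i] += tr.value[node];
    }
  }
  return out / static_cast<double>(trees.size());
}

// Per-row, per-feature SHAP values averaged over trees, plus the base
// value (cover-weighted mean leaf value). base + rowSums(phi) equals the
// forest margin for each row.
// [[Rcpp::export]]
List cpp_forest_shap(List trees, NumericMatrix X) {
  const int n = X.nrow(), k = X.ncol(), m = trees.size();
  NumericMatrix phi(n, k);
  double base = 0.0;
  std::vector<double> xrow(k);
  for (int t = 0; t < m; ++t) {
    const List tree = trees[t];
    const Tree tr = unpack_tree(tree);
    const int nnode = Rf_length(tree["left"]);
    double leaf_mass = 0.0;
    for (int j = 0; j < nnode; ++j)
      if (tr.left[j] < 0) leaf_mass += tr.cover[j] * tr.value[j];
    base += leaf_mass / tr.cover[0];
    const int depth = tree_depth(tr, 0);
    std::vector<PathElement> buf((depth + 3) * (depth + 4) / 2);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < k; ++j) xrow[j] = X(i, j);
      std::vector<double> phirow(k, 0.0);
      shap_recurse(tr, xrow.data(), phirow.data(), 0, 0, buf.data(),
                   1.0, 1.0, -1);
      for (int j = 0; j < k; ++j) phi(i, j) += phirow[j];
    }
  }
  phi = phi / static_cast<double>(m);
  return List::create(_["phi"] = phi, _["base"] = base / m);
}

static void rank_average(const std::vector<double> &v, std::vector<double> &r,
                         std::vector<int> &idx) {
  const int n = v.size();
  idx.resize(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return v[a] < v[b]; });
  r.resize(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && v[idx[j + 1]] == v[idx[i]]) ++j;
    const double avg = (i + j) / 2.0 + 1.0;
    for (int t = i; t <= j; ++t) r[idx[t]] = avg;
    i = j + 1;
  }
}

// Bootstrap distribution of Spearman's rho for one feature pair, resampling
// rows with replacement under R's RNG.
// [[Rcpp::export]]
NumericVector cpp_boot_spearman(NumericVector x, NumericVector y, int nboot) {
  const int n = x.size();
  NumericVector out(nboot);
  std::vector<double> xb(n), yb(n), rx, ry;
  std::vector<int> idx;
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) {
      const int j = static_cast<int>(unif_rand() * n);
      xb[i] = x[j];
      yb[i] = y[j];
    }
    rank_average(xb, rx, idx);
    rank_average(yb, ry, idx);
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    for (int i = 0; i < n; ++i) {
      sx += rx[i]; sy += ry[i];
      sxx += rx[i] * rx[i]; syy += ry[i] * ry[i];
      sxy += rx[i] * ry[i];
    }
    const double cov = sxy - sx * sy / n;
    const double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
    out[b] = (vx > 0 && vy > 0) ? cov / std::sqrt(vx * vy) : NA_REAL;
  }
  return out;
}
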