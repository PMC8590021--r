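#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Plain array view of one regression tree. "x <= split" goes left.
struct Tree {
  IntegerVector left, right, feature;
  NumericVector split, value;
};

static std::vector<Tree> unpack(const List& trees) {
  std::vector<Tree> out;
  out.reserve(trees.size());
  for (R_xlen_t t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    Tree tree;
    tree.left = tr["left"];
    tree.right = tr["right"];
    tree.feature = tr["feature"];
    tree.split = tr["split"];
    tree.value = tr["value"];
    out.push_back(tree);
  }
  return out;
}

static double predict_tree(const Tree& tr, const double* data,
                           R_xlen_t nrow, R_xlen_t row) {
  int node = 0;
  while (tr.feature[node] >= 0) {
    double v = data[row + (R_xlen_t)tr.feature[node] * nrow];
    node = (v <= tr.split[node]) ? tr.left[node] : tr.right[node];
  }
  return tr.value[node];
}

// [[Rcpp::export]]
NumericVector ensemble_predict_cpp(List trees, NumericMatrix x) {
  std::vector<Tree> ts = unpack(trees);
  R_xlen_t n = x.nrow();
  NumericVector out(n);
  const double* xp = x.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    double s = 0.0;
    for (size_t t = 0; t < ts.size(); ++t)
      s += predict_tree(ts[t], xp, n, i);
    out[i] = s / ts.size();
  }
  return out;
}

// Shapley weight q(a, b) = a! b! / (a + b + 1)!  -- the probability mass a
// leaf requiring `a` further foreground features and `b` background
// features receives under the Shapley kernel.
struct QTable {
  std::vector<double> lf;  // log factorials
  QTable(int n) : lf(n + 2, 0.0) {
    for (int i = 1; i < (int)lf.size(); ++i)
      lf[i] = lf[i - 1] + std::log((double)i);
  }
  double q(int a, int b) const {
    return std::exp(lf[a] + lf[b] - lf[a + b + 1]);
  }
};

// State of the recursive path walk: which features are currently forced to
// their foreground (x) or background (z) value.
struct Walker {
  const Tree* tr;
  const double* x;   // foreground row (stride nx)
  const double* z;   // background row (stride nz)
  R_xlen_t xi, zi, nx, nz;
  std::vector<int> state;      // 0 free, 1 forced-x, 2 forced-z
  std::vector<int> ulist, vlist;
  double* phi;                 // per-feature accumulator (stride 1)
  const QTable* qt;

  void leaf(double val) {
    int u = (int)ulist.size(), v = (int)vlist.size();
    if (u + v == 0) return;  // reachable regardless; no attribution
    for (int f : ulist) phi[f] += val * qt->q(u - 1, v);
    for (int f : vlist) phi[f] -= val * qt->q(v - 1, u);
  }

  void walk(int node) {
    int f = tr->feature[node];
    if (f < 0) { leaf(tr->value[node]); return; }
    double xv = x[xi + (R_xlen_t)f * nx];
    double zv = z[zi + (R_xlen_t)f * nz];
    bool xleft = xv <= tr->split[node];
    bool zleft = zv <= tr->split[node];
    if (xleft == zleft) {
      walk(xleft ? tr->left[node] : tr->right[node]);
      return;
    }
    // branch where the feature takes its foreground value
    if (state[f] != 2) {
      bool pushed = (state[f] == 0);
      if (pushed) { state[f] = 1; ulist.push_back(f); }
      walk(xleft ? tr->left[node] : tr->right[node]);
      if (pushed) { state[f] = 0; ulist.pop_back(); }
    }
    // branch where the feature keeps its background value
    if (state[f] != 1) {
      bool pushed = (state[f] == 0);
      if (pushed) { state[f] = 2; vlist.push_back(f); }
      walk(zleft ? tr->left[node] : tr->right[node]);
      if (pushed) { state[f] = 0; vlist.pop_back(); }
    }
  }
};

// Exact interventional Shapley values of a tree ensemble: for every
// (sample, background row, tree) the leaf-wise closed form is accumulated,
// then averaged over background rows and trees (the ensemble prediction is
// the tree mean). base_value is the mean ensemble prediction over the
// background.
// [[Rcpp::export]]
List treeshap_interventional_cpp(List trees, NumericMatrix samples,
                                 NumericMatrix background) {
  std::vector<Tree> ts = unpack(trees);
  R_xlen_t n = samples.nrow(), p = samples.ncol(), nb = background.nrow();
  NumericMatrix phi(n, p);
  QTable qt(128);

  std::vector<double> acc(p);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t t = 0; t < ts.size(); ++t) {
      Walker w;
      w.tr = &ts[t];
      w.x = samples.begin();
      w.z = background.begin();
      w.xi = i; w.nx = n; w.nz = nb;
      w.state.assign(p, 0);
      w.phi = acc.data();
      w.qt = &qt;
      for (R_xlen_t zi = 0; zi < nb; ++zi) {
        w.zi = zi;
        w.walk(0);
      }
    }
    double norm = (double)ts.size() * (double)nb;
    for (R_xlen_t j = 0; j < p; ++j) phi(i, j) = acc[j] / norm;
  }

  double base = 0.0;
  const double* zp = background.begin();
  for (R_xlen_t zi = 0; zi < nb; ++zi)
    for (size_t t = 0; t < ts.size(); ++t)
      base += predict_tree(ts[t], zp, nb, zi);
  base /= (double)ts.size() * (double)nb;

  return List::create(Named("values") = phi, Named("base_value") = base);
}
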