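// Exact interventional Shapley attribution for probability forests.
//
// For one foreground cell x, one background cell z and one tree, the
// coalition game is v(S) = t(w) where w takes x's value on features in S and
// z's elsewhere. A leaf L with path constraints is reached under S iff every
// path feature whose constraints x satisfies but z does not ("in"-features,
// P) is in S, and every feature z satisfies but x does not (Q) is out of S;
// features both satisfy are irrelevant, and a feature neither satisfies makes
// L unreachable. The Shapley value of that indicator game is
//   phi_i = (p-1)! q! / (p+q)!        for i in P
//   phi_j = -p! (q-1)! / (p+q)!       for j in Q     (p = |P|, q = |Q|),
// so one depth-first pass per (x, z, tree) accumulates exact attributions,
// leaf by leaf. Averaging over the background set gives phi with
// base + sum(phi) = f(x) exactly (per-leaf efficiency telescopes).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> left, right, feat;
  std::vector<double> thr;
  std::vector<double> probs;  // n_nodes x K, column-major
  int n_nodes;
};

std::vector<Tree> unpack_forest(const List& forest, int n_classes) {
  std::vector<Tree> trees(forest.size());
  for (int k = 0; k < forest.size(); ++k) {
    List tr = forest[k];
    Tree& t = trees[k];
    t.left = as<std::vector<int>>(tr["left"]);
    t.right = as<std::vector<int>>(tr["right"]);
    t.feat = as<std::vector<int>>(tr["feature"]);
    t.thr = as<std::vector<double>>(tr["threshold"]);
    NumericMatrix pm = tr["probs"];
    if (pm.ncol() != n_classes) stop("tree probs have wrong class count");
    t.n_nodes = pm.nrow();
    t.probs.assign(pm.begin(), pm.end());
    if ((int)t.left.size() != t.n_nodes) stop("malformed tree arrays");
  }
  return trees;
}

// Weight tables W_in[p][q], W_out[p][q] for p+q <= maxd.
struct ShapWeights {
  int maxd;
  std::vector<double> win, wout;  // (maxd+1) x (maxd+1), index p*(maxd+1)+q
  explicit ShapWeights(int maxd_) : maxd(maxd_) {
    win.assign((maxd + 1) * (maxd + 1), 0.0);
    wout.assign((maxd + 1) * (maxd + 1), 0.0);
    for (int p = 0; p <= maxd; ++p)
      for (int q = 0; q + p <= maxd; ++q) {
        if (p >= 1)
          win[p * (maxd + 1) + q] =
            std::exp(std::lgamma(p) + std::lgamma(q + 1) -
                     std::lgamma(p + q + 1));
        if (q >= 1)
          wout[p * (maxd + 1) + q] =
            std::exp(std::lgamma(p + 1) + std::lgamma(q) -
                     std::lgamma(p + q + 1));
      }
  }
};

struct Traverser {
  const Tree* t;
  const double* x;
  const double* z;
  int n_classes;
  const ShapWeights* W;
  // per-feature path state (stamp-versioned so reset is O(1))
  std::vector<int> stamp;
  std::vector<char> okx, okz;
  std::vector<int> path_feats;
  int cur;
  double* phi;       // p_features x K, column-major
  double tree_weight;

  void leaf(int node) {
    int p = 0, q = 0;
    for (int f : path_feats) {
      if (okx[f] && !okz[f]) ++p;
      else if (!okx[f] && okz[f]) ++q;
    }
    if (p == 0 && q == 0) return;  // leaf reached by every coalition
    int side = W->maxd + 1;
    double w_in = W->win[p * side + q];
    double w_out = W->wout[p * side + q];
    int np = stamp.size();
    for (int f : path_feats) {
      double w;
      if (okx[f] && !okz[f]) w = w_in;
      else if (!okx[f] && okz[f]) w = -w_out;
      else continue;
      for (int c = 0; c < n_classes; ++c)
        phi[f + (size_t)np * c] +=
          w * tree_weight * t->probs[node + (size_t)t->n_nodes * c];
    }
  }

  void rec(int node) {
    if (t->left[node] < 0) { leaf(node); return; }
    int f = t->feat[node];
    double cut = t->thr[node];
    bool ax = x[f] <= cut, az = z[f] <= cut;
    descend(t->left[node], f, ax, az);
    descend(t->right[node], f, !ax, !az);
  }

  void descend(int child, int f, bool sx, bool sz) {
    bool fresh = stamp[f] != cur;
    char ox = fresh ? 1 : okx[f];
    char oz = fresh ? 1 : okz[f];
    char nx = ox && sx, nz = oz && sz;
    if (!nx && !nz) return;  // no coalition reaches this subtree
    if (fresh) { stamp[f] = cur; path_feats.push_back(f); }
    okx[f] = nx; okz[f] = nz;
    rec(child);
    okx[f] = ox; okz[f] = oz;
    if (fresh) { path_feats.pop_back(); stamp[f] = cur - 1; }
  }
};

void predict_row(const std::vector<Tree>& trees, const double* x,
                 int n_classes, double* out) {
  for (int c = 0; c < n_classes; ++c) out[c] = 0.0;
  for (const Tree& t : trees) {
    int node = 0;
    while (t.left[node] >= 0)
      node = (x[t.feat[node]] <= t.thr[node]) ? t.left[node] : t.right[node];
    for (int c = 0; c < n_classes; ++c)
      out[c] += t.probs[node + (size_t)t.n_nodes * c];
  }
  double inv = 1.0 / trees.size();
  for (int c = 0; c < n_classes; ++c) out[c] *= inv;
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forest_predict(List forest, NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  List tr0 = forest[0];
  NumericMatrix pm0 = tr0["probs"];
  int K = pm0.ncol();
  std::vector<Tree> trees = unpack_forest(forest, K);
  NumericMatrix out(n, K);
  std::vector<double> row(p), pr(K);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) row[j] = X(i, j);
    predict_row(trees, row.data(), K, pr.data());
    for (int c = 0; c < K; ++c) out(i, c) = pr[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_shap_interventional(List forest, NumericMatrix X,
                                      NumericMatrix BG, int n_classes) {
  int n = X.nrow(), p = X.ncol(), nb = BG.nrow();
  if (BG.ncol() != p) stop("background and foreground gene spaces differ");
  if (nb < 1) stop("empty background");
  std::vector<Tree> trees = unpack_forest(forest, n_classes);

  // longest root-to-leaf path bounds p + q
  int maxd = 1;
  for (const Tree& t : trees) {
    std::vector<int> depth(t.n_nodes, 0);
    int dmax = 0;
    for (int v = 0; v < t.n_nodes; ++v) {
      if (t.left[v] >= 0) {
        depth[t.left[v]] = depth[v] + 1;
        depth[t.right[v]] = depth[v] + 1;
      } else if (depth[v] > dmax) dmax = depth[v];
    }
    if (dmax > maxd) maxd = dmax;
  }
  ShapWeights W(maxd + 1);

  NumericVector out(Dimension(n, p, n_classes));  // zero-initialized
  std::vector<double> phi((size_t)p * n_classes);
  std::vector<double> xrow(p), zrow(p);

  Traverser tv;
  tv.n_classes = n_classes;
  tv.W = &W;
  tv.stamp.assign(p, -1);
  tv.okx.assign(p, 1);
  tv.okz.assign(p, 1);
  tv.cur = 0;
  tv.tree_weight = 1.0 / (trees.size() * (double)nb);

  for (int i = 0; i < n; ++i) {
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    tv.x = xrow.data();
    tv.phi = phi.data();
    for (int b = 0; b < nb; ++b) {
      for (int j = 0; j < p; ++j) zrow[j] = BG(b, j);
      tv.z = zrow.data();
      for (const Tree& t : trees) {
        tv.t = &t;
        ++tv.cur;
        tv.path_feats.clear();
        tv.rec(0);
      }
    }
    for (int c = 0; c < n_classes; ++c)
      for (int j = 0; j < p; ++j)
        out[i + (size_t)n * j + (size_t)n * p * c] = phi[j + (size_t)p * c];
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
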