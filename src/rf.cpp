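// Compact regression random forest tuned for the very small design matrices
// (n <= a few hundred, p <= a few hundred) that the multi-seed stability
// selection procedures fit tens of thousands of times. CART variance
// splitting with bootstrap resampling, per-split feature subsampling,
// midpoint thresholds, min_samples_split / min_samples_leaf stopping and
// normalized impurity (Gini-for-regression) importance.

#include <Rcpp.h>\n#include <cstring>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

// xoshiro-free small RNG: splitmix64 seeded mt19937-like stream. We avoid
// R's RNG so fits are reproducible from an explicit integer seed and do not
// disturb the caller's random stream.
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform integer in [0, n)
  int unif_int(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct Node {
  int feat;      // -1 for leaf
  double thr;
  int left, right;
  double value;
};

struct Tree {
  std::vector<Node> nodes;
};

struct SplitResult {
  bool found = false;
  int feat = -1;
  double thr = 0.0;
  double gain = 0.0;   // decrease in total SS
  double left_mean = 0.0, right_mean = 0.0;
  int n_left = 0;
};

}  // namespace

// Exact histogram split finding: each feature is pre-binned once per fit
// into its sorted unique values, so per-node split search is a linear pass
// over node samples plus a bin scan -- no per-node sorting. Produces the
// same trees as a sorted exhaustive scan.
struct BinnedX {
  int n_rows = 0, p = 0, max_nb = 0;
  std::vector<int> nb;        // #unique values per feature
  std::vector<int> off;       // offset of feature f in uvals
  std::vector<double> uvals;  // pooled sorted unique values
  std::vector<uint16_t> bx;   // n_rows x p bin indices (column-major)
};

static void bin_features(const double* X, int n_rows, int p, BinnedX& B) {
  B.n_rows = n_rows; B.p = p;
  B.nb.assign(p, 0); B.off.assign(p, 0);
  B.uvals.clear();
  B.bx.assign(static_cast<size_t>(n_rows) * p, 0);
  std::vector<double> col(n_rows);
  std::vector<int> ord(n_rows);
  for (int f = 0; f < p; ++f) {
    const double* xc = X + static_cast<size_t>(f) * n_rows;
    for (int i = 0; i < n_rows; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return xc[a] < xc[b]; });
    B.off[f] = static_cast<int>(B.uvals.size());
    int nb = 0;
    for (int k = 0; k < n_rows; ++k) {
      int row = ord[k];
      if (nb == 0 || xc[row] != B.uvals.back()) {
        B.uvals.push_back(xc[row]);
        ++nb;
      }
      B.bx[static_cast<size_t>(f) * n_rows + row] =
          static_cast<uint16_t>(nb - 1);
    }
    B.nb[f] = nb;
    if (nb > B.max_nb) B.max_nb = nb;
  }
}

// Grow one tree on the bootstrap sample stored in `idx`.
// Accumulates impurity importance into `imp`.
struct Bin { double sum; int cnt; };

static void build_tree(const double* X, const BinnedX& B, const double* y,
                       std::vector<int>& idx, std::vector<double>& yn,
                       Rng& rng, int mtry, int min_split, int min_leaf,
                       int n_total, Tree& tree, std::vector<double>& imp,
                       std::vector<int>& feat_pool,
                       std::vector<Bin>& bins, std::vector<int>& occ) {
  const int n_rows = B.n_rows, p = B.p;
  struct Job { int start, end, node; };
  std::vector<Job> stack;

  auto node_stats = [&](int s, int e, double& mean, double& ss) {
    double sum = 0.0, sum2 = 0.0;
    for (int k = s; k < e; ++k) {
      double v = yn[k];
      sum += v; sum2 += v * v;
    }
    int n = e - s;
    mean = sum / n;
    ss = sum2 - sum * sum / n;
  };

  tree.nodes.clear();
  tree.nodes.push_back(Node{-1, 0.0, -1, -1, 0.0});
  stack.push_back(Job{0, static_cast<int>(idx.size()), 0});

  while (!stack.empty()) {
    Job job = stack.back(); stack.pop_back();
    int s = job.start, e = job.end, n = e - s;
    double mean, ss;
    node_stats(s, e, mean, ss);
    tree.nodes[job.node].value = mean;

    if (n < min_split || ss <= 1e-12) continue;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int i = 0; i < p; ++i) feat_pool[i] = i;
    SplitResult best;
    for (int t = 0; t < mtry; ++t) {
      int j = t + rng.unif_int(p - t);
      std::swap(feat_pool[t], feat_pool[j]);
      int f = feat_pool[t];
      const uint16_t* bxf = B.bx.data() + static_cast<size_t>(f) * n_rows;
      const double* uv = B.uvals.data() + B.off[f];

      // histogram over this feature's value bins; occupied bins listed in occ
      int n_occ = 0;
      for (int k = s; k < e; ++k) {
        int b = bxf[idx[k]];
        if (bins[b].cnt == 0) { bins[b].sum = 0.0; occ[n_occ++] = b; }
        ++bins[b].cnt;
        bins[b].sum += yn[k];
      }
      if (n_occ < 2) { bins[occ[0]].cnt = 0; continue; }  // constant in node
      if (n_occ <= 24) {  // insertion sort for the common small case
        for (int a = 1; a < n_occ; ++a) {
          int v = occ[a], b2 = a - 1;
          while (b2 >= 0 && occ[b2] > v) { occ[b2 + 1] = occ[b2]; --b2; }
          occ[b2 + 1] = v;
        }
      } else {
        std::sort(occ.begin(), occ.begin() + n_occ);
      }

      const double sum_total = mean * n;
      double sum_l = 0.0;
      int nl = 0;
      for (int q = 0; q < n_occ; ++q) {
        int b = occ[q];
        if (q > 0) {
          // candidate split between occupied bins occ[q-1] and b
          int nr = n - nl;
          if (nl >= min_leaf && nr >= min_leaf) {
            double sum_r = sum_total - sum_l;
            // maximizing sum_l^2/nl + sum_r^2/nr maximizes SS decrease
            double crit = sum_l * sum_l / nl + sum_r * sum_r / nr;
            double gain = crit - sum_total * sum_total / n;
            if (!best.found || gain > best.gain) {
              best.found = true;
              best.feat = f;
              best.thr = 0.5 * (uv[occ[q - 1]] + uv[b]);
              best.gain = gain;
              best.left_mean = sum_l / nl;
              best.right_mean = sum_r / nr;
              best.n_left = nl;
            }
          }
        }
        sum_l += bins[b].sum;
        nl += bins[b].cnt;
      }
      for (int q = 0; q < n_occ; ++q) bins[occ[q]].cnt = 0;  // reset
    }
    if (!best.found || best.gain <= 1e-12) continue;

    // in-place partition of idx[s..e) (yn kept parallel to idx)
    const double* xb = X + static_cast<size_t>(best.feat) * n_rows;
    int lo = s, hi = e - 1;
    while (lo <= hi) {
      if (xb[idx[lo]] <= best.thr) { ++lo; }
      else {
        std::swap(idx[lo], idx[hi]);
        std::swap(yn[lo], yn[hi]);
        --hi;
      }
    }
    int mid = lo;  // idx[s..mid) left, idx[mid..e) right
    if (mid == s || mid == e) continue;  // numerical guard

    int li = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, best.left_mean});
    int ri = static_cast<int>(tree.nodes.size());
    tree.nodes.push_back(Node{-1, 0.0, -1, -1, best.right_mean});
    tree.nodes[job.node].feat = best.feat;
    tree.nodes[job.node].thr = best.thr;
    tree.nodes[job.node].left = li;
    tree.nodes[job.node].right = ri;

    // weighted impurity decrease (scikit-learn convention)
    imp[best.feat] += (static_cast<double>(n) / n_total) * (best.gain / n);

    stack.push_back(Job{s, mid, li});
    stack.push_back(Job{mid, e, ri});
  }
}

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, NumericVector y, int num_trees, int mtry,
                int min_split, int min_leaf, double seed) {
  const int n = X.nrow();
  if (n != y.size()) stop("X and y dimensions disagree");
  if (n < 2) stop("need at least two samples");
  if (mtry < 1 || mtry > X.ncol()) stop("invalid mtry");

  Rng rng(static_cast<uint64_t>(seed));
  std::vector<int> idx(n);
  std::vector<int> feat_pool(X.ncol());
  std::vector<double> imp(X.ncol(), 0.0);

  const double* Xp = REAL(X);
  const double* yp = REAL(y);
  BinnedX B;
  bin_features(Xp, n, X.ncol(), B);
  std::vector<Bin> bins(B.max_nb, Bin{0.0, 0});
  std::vector<int> occ(B.max_nb, 0);
  std::vector<double> yn(n);

  // flattened forest: per-node arrays with per-tree offsets
  std::vector<int> feat, left, right, tree_offset;
  std::vector<double> thr, value;
  Tree tree;
  for (int t = 0; t < num_trees; ++t) {
    for (int k = 0; k < n; ++k) {   // bootstrap
      idx[k] = rng.unif_int(n);
      yn[k] = yp[idx[k]];
    }
    build_tree(Xp, B, yp, idx, yn, rng, mtry, min_split, min_leaf, n,
               tree, imp, feat_pool, bins, occ);
  tree_offset.push_back(static_cast<int>(feat.size()));
    for (const Node& nd : tree.nodes) {
      feat.push_back(nd.feat);
      thr.push_back(nd.thr);
      left.push_back(nd.left);
      right.push_back(nd.right);
      value.push_back(nd.value);
    }
  }
  tree_offset.push_back(static_cast<int>(feat.size()));

  double imp_sum = 0.0;
  for (double v : imp) imp_sum += v;
  NumericVector importance(X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    importance[j] = imp_sum > 0 ? imp[j] / num_trees : 0.0;
  // report raw (per-tree averaged) decreases; normalization done in R

  return List::create(
      _["feat"] = wrap(feat), _["thr"] = wrap(thr), _["left"] = wrap(left),
      _["right"] = wrap(right), _["value"] = wrap(value),
      _["tree_offset"] = wrap(tree_offset), _["num_trees"] = num_trees,
      _["importance"] = importance);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  IntegerVector feat = forest["feat"], left = forest["left"],
                right = forest["right"], off = forest["tree_offset"];
  NumericVector thr = forest["thr"], value = forest["value"];
  int num_trees = forest["num_trees"];
  int n = X.nrow();
  NumericVector out(n);
  const double* Xp = REAL(X);
  const int *fp = INTEGER(feat), *lp = INTEGER(left), *rp = INTEGER(right),
            *op = INTEGER(off);
  const double *tp = REAL(thr), *vp = REAL(value);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int t = 0; t < num_trees; ++t) {
      int o = op[t];
      int node = o;
      while (fp[node] >= 0) {
        double x = Xp[static_cast<size_t>(fp[node]) * n + i];
        node = o + (x <= tp[node] ? lp[node] : rp[node]);
      }
      acc += vp[node];
    }
    out[i] = acc / num_trees;
  }
  return out;
}
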