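#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Counter-based PRNG: splitmix64 stream. Deterministic and independent of
// R's RNG so forests are bit-reproducible regardless of calling context.
static inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t state;
  double cached;
  bool has_cached;
  explicit Rng(uint64_t seed) : state(seed), cached(0.0), has_cached(false) {}
  // uniform on [0, 1)
  double unif() {
    return (double)(splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
  }
  // standard normal via Box-Muller
  double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u1 = unif();
    while (u1 <= 0.0) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    has_cached = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct TreeBuild {
  int d;
  std::vector<double> normals;  // n_nodes * d, row-major
  std::vector<double> points;   // n_nodes * d, row-major
  std::vector<int> left, right, size;  // 1-based child indices, 0 = leaf
  int new_node() {
    left.push_back(0); right.push_back(0); size.push_back(0);
    for (int j = 0; j < d; ++j) { normals.push_back(0.0); points.push_back(0.0); }
    return (int)left.size() - 1;
  }
};

static void build_node(TreeBuild &T, int node, const NumericMatrix &X,
                       std::vector<int> &idx, int lo, int hi,
                       int depth, int max_depth, Rng &rng) {
  const int n = hi - lo, d = T.d;
  T.size[node] = n;
  if (depth >= max_depth || n <= 1) return;  // leaf

  // node bounding box
  std::vector<double> mn(d), mx(d);
  for (int j = 0; j < d; ++j) mn[j] = mx[j] = X(idx[lo], j);
  for (int k = lo + 1; k < hi; ++k)
    for (int j = 0; j < d; ++j) {
      double v = X(idx[k], j);
      if (v < mn[j]) mn[j] = v;
      if (v > mx[j]) mx[j] = v;
    }
  bool degenerate = true;
  for (int j = 0; j < d; ++j) if (mx[j] > mn[j]) { degenerate = false; break; }
  if (degenerate) return;  // duplicated points -> leaf

  // random hyperplane: normal uniform on the unit sphere, intercept uniform
  // inside the bounding box; redraw if the cut fails to separate the points
  std::vector<double> nv(d), pv(d);
  std::vector<int> L, R;
  for (int attempt = 0; attempt < 16; ++attempt) {
    double norm2 = 0.0;
    for (int j = 0; j < d; ++j) { nv[j] = rng.norm(); norm2 += nv[j] * nv[j]; }
    if (norm2 <= 0.0) continue;
    double inv = 1.0 / std::sqrt(norm2);
    for (int j = 0; j < d; ++j) nv[j] *= inv;
    for (int j = 0; j < d; ++j) pv[j] = mn[j] + rng.unif() * (mx[j] - mn[j]);

    L.clear(); R.clear();
    for (int k = lo; k < hi; ++k) {
      double dot = 0.0;
      for (int j = 0; j < d; ++j) dot += (X(idx[k], j) - pv[j]) * nv[j];
      if (dot <= 0.0) L.push_back(idx[k]); else R.push_back(idx[k]);
    }
    if (L.empty() || R.empty()) continue;

    for (size_t k = 0; k < L.size(); ++k) idx[lo + k] = L[k];
    for (size_t k = 0; k < R.size(); ++k) idx[lo + L.size() + k] = R[k];
    int lnode = T.new_node();
    int rnode = T.new_node();
    for (int j = 0; j < d; ++j) {
      T.normals[(size_t)node * d + j] = nv[j];
      T.points[(size_t)node * d + j]  = pv[j];
    }
    T.left[node]  = lnode + 1;
    T.right[node] = rnode + 1;
    int mid = lo + (int)L.size();
    build_node(T, lnode, X, idx, lo, mid, depth + 1, max_depth, rng);
    build_node(T, rnode, X, idx, mid, hi, depth + 1, max_depth, rng);
    return;
  }
  // could not find a separating cut -> leaf
}

// [[Rcpp::export]]
List eif_fit_cpp(NumericMatrix X, int n_trees, int psi, int max_depth,
                 double seed) {
  const int n = X.nrow(), d = X.ncol();
  List trees(n_trees);
  const uint64_t base = (uint64_t)(int64_t)std::llround(seed);
  for (int t = 0; t < n_trees; ++t) {
    // expand the global seed into one independent stream per tree
    uint64_t s = base ^ ((uint64_t)(t + 1) * 0xD1B54A32D192ED03ULL);
    Rng rng(splitmix64(s));

    // uniform subsample of size psi without replacement (partial Fisher-Yates)
    std::vector<int> pool(n);
    for (int i = 0; i < n; ++i) pool[i] = i;
    const int m = psi < n ? psi : n;
    std::vector<int> idx(m);
    for (int i = 0; i < m; ++i) {
      int j = i + (int)(rng.unif() * (double)(n - i));
      if (j >= n) j = n - 1;
      std::swap(pool[i], pool[j]);
      idx[i] = pool[i];
    }

    TreeBuild T;
    T.d = d;
    int root = T.new_node();
    build_node(T, root, X, idx, 0, m, 0, max_depth, rng);

    const int nn = (int)T.left.size();
    NumericMatrix nm(nn, d), pm(nn, d);
    for (int k = 0; k < nn; ++k)
      for (int j = 0; j < d; ++j) {
        nm(k, j) = T.normals[(size_t)k * d + j];
        pm(k, j) = T.points[(size_t)k * d + j];
      }
    trees[t] = List::create(
      _["normal"] = nm,
      _["point"]  = pm,
      _["left"]   = IntegerVector(T.left.begin(), T.left.end()),
      _["right"]  = IntegerVector(T.right.begin(), T.right.end()),
      _["size"]   = IntegerVector(T.size.begin(), T.size.end()));
  }
  return trees;
}

// Mean isolation path length per query point.
// ctab[k] (0-based) = c(k), the path-length adjustment for a leaf of size k.
// [[Rcpp::export]]
NumericVector eif_path_cpp(List trees, NumericMatrix X, NumericVector ctab) {
  const int n = X.nrow(), d = X.ncol(), nt = trees.size();
  std::vector<double> acc(n, 0.0);
  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    NumericMatrix nm = tr["normal"], pm = tr["point"];
    IntegerVector left = tr["left"], right = tr["right"], size = tr["size"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      double depth = 0.0;
      while (left[node] != 0) {
        double dot = 0.0;
        for (int j = 0; j < d; ++j) dot += (X(i, j) - pm(node, j)) * nm(node, j);
        node = (dot <= 0.0 ? left[node] : right[node]) - 1;
        depth += 1.0;
      }
      int sz = size[node];
      acc[i] += depth + (sz < ctab.size() ? ctab[sz] : ctab[ctab.size() - 1]);
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / (double)nt;
  return out;
}

// Optimal string alignment (restricted Damerau-Levenshtein) distance.
// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int q = 0; q < n; ++q) {
    std::string s1 = as<std::string>(a[q]);
    std::string s2 = as<std::string>(b[q]);
    const int l1 = (int)s1.size(), l2 = (int)s2.size();
    std::vector<int> d((l1 + 1) * (l2 + 1));
    const int W = l2 + 1;
    for (int i = 0; i <= l1; ++i) d[i * W] = i;
    for (int j = 0; j <= l2; ++j) d[j] = j;
    for (int i = 1; i <= l1; ++i) {
      for (int j = 1; j <= l2; ++j) {
        int cost = (s1[i - 1] == s2[j - 1]) ? 0 : 1;
        int v = std::min(std::min(d[(i - 1) * W + j] + 1, d[i * W + j - 1] + 1),
                         d[(i - 1) * W + j - 1] + cost);
        if (i > 1 && j > 1 && s1[i - 1] == s2[j - 2] && s1[i - 2] == s2[j - 1])
          v = std::min(v, d[(i - 2) * W + j - 2] + 1);
        d[i * W + j] = v;
      }
    }
    out[q] = d[l1 * W + l2];
  }
  return out;
}
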