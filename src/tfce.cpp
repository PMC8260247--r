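#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_map>
using namespace Rcpp;

// 6-connectivity neighbor lists for mask voxels on a 3-D grid.
// maskIdx holds 1-based linear (column-major) grid indices.
static std::vector<std::vector<int> > mask_neighbors(const IntegerVector &maskIdx,
                                                     const IntegerVector &dims) {
  const int nx = dims[0], ny = dims[1];
  const int V = maskIdx.size();
  std::unordered_map<int, int> pos;
  pos.reserve(V * 2);
  for (int i = 0; i < V; ++i) pos[maskIdx[i]] = i;
  std::vector<std::vector<int> > nb(V);
  const long plane = (long)nx * ny;
  for (int i = 0; i < V; ++i) {
    long idx0 = maskIdx[i] - 1;
    int x = idx0 % nx, y = (idx0 / nx) % ny;
    long z = idx0 / plane;
    const long cand[6] = {
      x > 0 ? idx0 - 1 : -1,
      x < nx - 1 ? idx0 + 1 : -1,
      y > 0 ? idx0 - nx : -1,
      y < ny - 1 ? idx0 + nx : -1,
      z > 0 ? idx0 - plane : -1,
      idx0 + plane
    };
    for (int c = 0; c < 6; ++c) {
      if (cand[c] < 0) continue;
      if (c == 5 && cand[c] >= plane * dims[2]) continue;
      std::unordered_map<int, int>::iterator it = pos.find((int)cand[c] + 1);
      if (it != pos.end()) nb[i].push_back(it->second);
    }
  }
  return nb;
}

struct UnionFind {
  std::vector<int> parent;
  std::vector<int> size;
  std::vector<char> active;
  UnionFind(int n) : parent(n), size(n, 1), active(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

// TFCE of the positive part of one map over the mask. Thresholds step
// from hmax down to dh where dh = hmax / nsteps; clusters use face
// (6-)connectivity. enhanced[v] = sum_h extent(h)^E h^H dh over h <= v.
static void tfce_one(const double *vals,
                     const std::vector<std::vector<int> > &nb,
                     double E, double H, int nsteps, double *out) {
  const int V = nb.size();
  double hmax = 0.0;
  for (int i = 0; i < V; ++i) {
    out[i] = 0.0;
    if (vals[i] > hmax) hmax = vals[i];
  }
  if (hmax <= 0.0) return;
  const double dh = hmax / nsteps;

  std::vector<int> ord(V);
  for (int i = 0; i < V; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [vals](int a, int b) { return vals[a] > vals[b]; });

  UnionFind uf(V);
  std::vector<int> activeList;
  activeList.reserve(V);
  int next = 0;
  for (int s = nsteps; s >= 1; --s) {
    const double h = s * dh;
    while (next < V && vals[ord[next]] >= h - 1e-12) {
      int v = ord[next++];
      uf.active[v] = 1;
      activeList.push_back(v);
      for (size_t j = 0; j < nb[v].size(); ++j)
        if (uf.active[nb[v][j]]) uf.unite(v, nb[v][j]);
    }
    if (activeList.empty()) continue;
    const double hH = std::pow(h, H) * dh;
    for (size_t j = 0; j < activeList.size(); ++j) {
      int v = activeList[j];
      out[v] += std::pow((double)uf.size[uf.find(v)], E) * hH;
    }
  }
}

// [[Rcpp::export(name = ".tfceCpp")]]
NumericVector tfce_cpp(NumericVector values, IntegerVector dims,
                       IntegerVector maskIdx, double E, double H,
                       int nsteps) {
  if (values.size() != maskIdx.size())
    stop("values and maskIdx lengths differ");
  std::vector<std::vector<int> > nb = mask_neighbors(maskIdx, dims);
  NumericVector out(values.size());
  tfce_one(REAL(values), nb, E, H, nsteps, REAL(out));
  return out;
}

// Max TFCE statistic for each row of a (permutation x voxel) matrix,
// sharing one neighbor structure across rows.
// [[Rcpp::export(name = ".tfceMaxBatchCpp")]]
NumericVector tfce_max_batch_cpp(NumericMatrix maps, IntegerVector dims,
                                 IntegerVector maskIdx, double E, double H,
                                 int nsteps) {
  const int P = maps.nrow(), V = maps.ncol();
  if (V != maskIdx.size()) stop("map columns and maskIdx lengths differ");
  std::vector<std::vector<int> > nb = mask_neighbors(maskIdx, dims);
  NumericVector mx(P);
  std::vector<double> row(V), enh(V);
  for (int p = 0; p < P; ++p) {
    for (int v = 0; v < V; ++v) row[v] = maps(p, v);
    tfce_one(row.data(), nb, E, H, nsteps, enh.data());
    double m = 0.0;
    for (int v = 0; v < V; ++v) if (enh[v] > m) m = enh[v];
    mx[p] = m;
  }
  return mx;
}

// Matched-activation draws: for each draw, sample k voxels without
// replacement from the strongly connected half and k from the weakly
// connected half, and compute the pooled two-sample t statistic of
// their activation values. Uses R's RNG so results are reproducible
// under set.seed(). Zero pooled variance is defined as t = 0.
// [[Rcpp::export(name = ".matchedDrawsCpp")]]
List matched_draws_cpp(IntegerVector highIdx, IntegerVector lowIdx,
                       NumericVector tvals, int k, int ndraws) {
  const int nh = highIdx.size(), nl = lowIdx.size();
  if (k > nh || k > nl) stop("k exceeds a half-split size");
  IntegerMatrix strong(ndraws, k), weak(ndraws, k);
  NumericVector tstat(ndraws);
  std::vector<int> hi(highIdx.begin(), highIdx.end());
  std::vector<int> lo(lowIdx.begin(), lowIdx.end());

  for (int d = 0; d < ndraws; ++d) {
    double s1 = 0, ss1 = 0, s2 = 0, ss2 = 0;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (nh - i));
      std::swap(hi[i], hi[j]);
      strong(d, i) = hi[i];
      double v = tvals[hi[i] - 1];
      s1 += v; ss1 += v * v;
    }
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (nl - i));
      std::swap(lo[i], lo[j]);
      weak(d, i) = lo[i];
      double v = tvals[lo[i] - 1];
      s2 += v; ss2 += v * v;
    }
    double m1 = s1 / k, m2 = s2 / k;
    double v1 = (ss1 - k * m1 * m1) / (k - 1);
    double v2 = (ss2 - k * m2 * m2) / (k - 1);
    double sp2 = (v1 + v2) / 2.0;  // pooled, equal n
    tstat[d] = sp2 > 0 ? (m1 - m2) / std::sqrt(sp2 * 2.0 / k) : 0.0;
  }
  return List::create(_["tstat"] = tstat, _["strong"] = strong,
                      _["weak"] = weak);
}
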