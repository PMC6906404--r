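#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cmath>
#include <cstring>
#include "rng.h"

using namespace Rcpp;
using radcell::Rng;

// Branching random-walk vessel tree on an n^3 voxel lattice. A persistent
// trunk enters at the -x face and crosses the volume; branch tips sprout
// along all painted paths and wander with their own persistence. Everything
// grows from one tree, so the network is connected by construction.

struct Tip { double p[3], d[3]; };

static inline void renorm(double *v) {
  double n = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
  if (n < 1e-12) { v[0] = 1; v[1] = 0; v[2] = 0; n = 1; }
  else { v[0] /= n; v[1] /= n; v[2] /= n; }
}

// [[Rcpp::export(".cpp_grow_vessels")]]
List cpp_grow_vessels(int n, double target_frac, double radius_vox,
                      double sigma_turn, double branch_p, double max_steps,
                      double seed) {
  Rng rng(seed);
  size_t nvox = (size_t)n * n * n;
  std::vector<uint8_t> occ(nvox, 0);
  std::vector<int> idx;
  long target = (long)std::ceil(target_frac * (double)nvox);
  idx.reserve(target + 256);

  int rv = (int)std::ceil(radius_vox);
  double r2 = radius_vox * radius_vox;
  long count = 0;
  auto paint = [&](const double *p) {
    int ci = (int)std::floor(p[0]), cj = (int)std::floor(p[1]),
        ck = (int)std::floor(p[2]);
    for (int i = std::max(0, ci - rv); i <= std::min(n - 1, ci + rv); ++i)
      for (int j = std::max(0, cj - rv); j <= std::min(n - 1, cj + rv); ++j)
        for (int k = std::max(0, ck - rv); k <= std::min(n - 1, ck + rv); ++k) {
          double dx = i + 0.5 - p[0], dy = j + 0.5 - p[1], dz = k + 0.5 - p[2];
          if (dx * dx + dy * dy + dz * dz > r2) continue;
          size_t v = (size_t)i + (size_t)n * ((size_t)j + (size_t)n * k);
          if (!occ[v]) { occ[v] = 1; idx.push_back((int)v); ++count; }
        }
  };

  std::vector<Tip> tips;
  Tip t0;
  t0.p[0] = 0.5; t0.p[1] = n * rng.runif(0.3, 0.7); t0.p[2] = n * rng.runif(0.3, 0.7);
  t0.d[0] = 1; t0.d[1] = 0; t0.d[2] = 0;
  tips.push_back(t0);
  paint(t0.p);

  double steps = 0;
  size_t cur = 0;
  while (count < target && steps < max_steps) {
    steps += 1;
    Tip &t = tips[cur];
    for (int k = 0; k < 3; ++k) t.d[k] += sigma_turn * rng.rnorm();
    renorm(t.d);
    for (int k = 0; k < 3; ++k) {
      t.p[k] += t.d[k];
      if (t.p[k] < 0) { t.p[k] = -t.p[k]; t.d[k] = -t.d[k]; }
      if (t.p[k] > n) { t.p[k] = 2 * n - t.p[k]; t.d[k] = -t.d[k]; }
    }
    paint(t.p);
    if (rng.u01() < branch_p) {
      Tip nt = t;
      for (int k = 0; k < 3; ++k) nt.d[k] = rng.rnorm();
      renorm(nt.d);
      tips.push_back(nt);
    }
    cur = (cur + 1) % tips.size();
  }

  // connected components (6-connectivity) over painted voxels
  int ncomp = 0;
  {
    std::vector<uint8_t> seen(nvox, 0);
    std::deque<int> q;
    for (size_t s = 0; s < idx.size(); ++s) {
      int v0 = idx[s];
      if (seen[v0]) continue;
      ++ncomp;
      seen[v0] = 1;
      q.push_back(v0);
      while (!q.empty()) {
        int v = q.front(); q.pop_front();
        int i = v % n, j = (v / n) % n, k = v / (n * n);
        const int di[6] = { 1, -1, 0, 0, 0, 0 };
        const int dj[6] = { 0, 0, 1, -1, 0, 0 };
        const int dk[6] = { 0, 0, 0, 0, 1, -1 };
        for (int e = 0; e < 6; ++e) {
          int ii = i + di[e], jj = j + dj[e], kk = k + dk[e];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= n || jj >= n || kk >= n) continue;
          size_t w = (size_t)ii + (size_t)n * ((size_t)jj + (size_t)n * kk);
          if (occ[w] && !seen[w]) { seen[w] = 1; q.push_back((int)w); }
        }
      }
    }
  }

  return List::create(_["idx"] = wrap(idx), _["achieved"] = (double)count / (double)nvox,
                      _["n_components"] = ncomp, _["steps"] = steps,
                      _["n_tips"] = (int)tips.size());
}

// exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// 1D lower envelope applied along each axis
static void dt1d(const int64_t *f, int64_t *d, int *v, double *zb, int n,
                 int64_t INF) {
  int q0 = 0;
  while (q0 < n && f[q0] >= INF) ++q0;
  if (q0 == n) { for (int q = 0; q < n; ++q) d[q] = INF; return; }
  int k = 0;
  v[0] = q0;
  zb[0] = -1e30; zb[1] = 1e30;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] >= INF) continue; // unreachable parabola
    double s;
    while (true) {
      int p = v[k];
      s = ((double)(f[q] - f[p]) + (double)q * q - (double)p * p) / (2.0 * (q - p));
      if (s <= zb[k]) --k; else break; // z[0] = -inf guarantees termination
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = f[p] + (int64_t)(q - p) * (q - p);
  }
}

// [[Rcpp::export(".cpp_vessel_distances")]]
NumericVector cpp_vessel_distances(int n, IntegerVector vessel_idx,
                                   IntegerVector query_idx) {
  size_t nvox = (size_t)n * n * n;
  const int64_t INF = (int64_t)4.5e18;
  std::vector<int64_t> sq(nvox, INF);
  for (R_xlen_t i = 0; i < vessel_idx.size(); ++i) sq[(size_t)vessel_idx[i]] = 0;

  std::vector<int64_t> f(n), d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);

  // pass 1: along x (fastest index)
  for (size_t j = 0; j < (size_t)n; ++j)
    for (size_t k = 0; k < (size_t)n; ++k) {
      size_t base = n * (j + (size_t)n * k);
      // simple two-sweep since values are 0 / INF
      int64_t run = INF;
      for (int i = 0; i < n; ++i) {
        if (sq[base + i] == 0) run = 0; else if (run < INF) run += 1;
        f[i] = run;
      }
      run = INF;
      for (int i = n - 1; i >= 0; --i) {
        if (sq[base + i] == 0) run = 0; else if (run < INF) run += 1;
        if (run < f[i]) f[i] = run;
        sq[base + i] = f[i] >= INF ? INF : f[i] * f[i];
      }
    }
  // pass 2: along y
  for (size_t i = 0; i < (size_t)n; ++i)
    for (size_t k = 0; k < (size_t)n; ++k) {
      bool any = false;
      for (int j = 0; j < n; ++j) {
        f[j] = sq[i + (size_t)n * ((size_t)j + (size_t)n * k)];
        if (f[j] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), v.data(), zb.data(), n, INF);
      for (int j = 0; j < n; ++j)
        sq[i + (size_t)n * ((size_t)j + (size_t)n * k)] = d[j];
    }
  // pass 3: along z
  for (size_t i = 0; i < (size_t)n; ++i)
    for (size_t j = 0; j < (size_t)n; ++j) {
      bool any = false;
      for (int k = 0; k < n; ++k) {
        f[k] = sq[i + (size_t)n * (j + (size_t)n * k)];
        if (f[k] < INF) any = true;
      }
      if (!any) continue;
      dt1d(f.data(), d.data(), v.data(), zb.data(), n, INF);
      for (int k = 0; k < n; ++k)
        sq[i + (size_t)n * (j + (size_t)n * k)] = d[k];
    }

  NumericVector out(query_idx.size());
  for (R_xlen_t q = 0; q < query_idx.size(); ++q)
    out[q] = std::sqrt((double)sq[(size_t)query_idx[q]]);
  return out;
}
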