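#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;
using radcell::Rng;

// Quasi-uniform points on the unit sphere (Fibonacci lattice).
static void fib_sphere(int n, std::vector<double> &pts) {
  pts.resize(3 * n);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    pts[3 * i] = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
}

// Proper rotation from a random unit quaternion.
static void random_rotation(Rng &rng, double R[9]) {
  double q[4], n2 = 0.0;
  do {
    n2 = 0.0;
    for (int i = 0; i < 4; ++i) { q[i] = rng.rnorm(); n2 += q[i] * q[i]; }
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  for (int i = 0; i < 4; ++i) q[i] /= n;
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2 * (y * y + z * z); R[1] = 2 * (x * y - w * z); R[2] = 2 * (x * z + w * y);
  R[3] = 2 * (x * y + w * z); R[4] = 1 - 2 * (x * x + z * z); R[5] = 2 * (y * z - w * x);
  R[6] = 2 * (x * z - w * y); R[7] = 2 * (y * z + w * x); R[8] = 1 - 2 * (x * x + y * y);
}

// world = center + R * (a .* u); R stored row-major (rows index world axes).
static inline void to_world(const double *c, const double *R, const double *a,
                            const double *u, double *out) {
  double v0 = a[0] * u[0], v1 = a[1] * u[1], v2 = a[2] * u[2];
  out[0] = c[0] + R[0] * v0 + R[1] * v1 + R[2] * v2;
  out[1] = c[1] + R[3] * v0 + R[4] * v1 + R[5] * v2;
  out[2] = c[2] + R[6] * v0 + R[7] * v1 + R[8] * v2;
}

// squared ellipsoid norm of point p relative to cell (c, R, a)
static inline double enorm2(const double *c, const double *R, const double *a,
                            const double *p) {
  double d0 = p[0] - c[0], d1 = p[1] - c[1], d2 = p[2] - c[2];
  double y0 = (R[0] * d0 + R[3] * d1 + R[6] * d2) / a[0];
  double y1 = (R[1] * d0 + R[4] * d1 + R[7] * d2) / a[1];
  double y2 = (R[2] * d0 + R[5] * d1 + R[8] * d2) / a[2];
  return y0 * y0 + y1 * y1 + y2 * y2;
}

// support half-width of the ellipsoid along world axis k
static inline double support_width(const double *R, const double *a, int k) {
  double s = 0.0;
  for (int j = 0; j < 3; ++j) {
    double v = R[3 * k + j] * a[j];
    s += v * v;
  }
  return std::sqrt(s);
}

// Random sequential addition of non-overlapping ellipsoids in a cube.
// Overlap test: bounding-sphere prescreen, inscribed-sphere quick reject,
// then mutual surface-point sampling against the interior test.
// [[Rcpp::export(".cpp_place_cells")]]
List cpp_place_cells(double box, int n_target, double d1_min, double d1_max,
                     double d23, int n_surf, double max_attempts, double seed) {
  Rng rng(seed);
  std::vector<double> usph;
  fib_sphere(n_surf, usph);

  std::vector<double> centers(3 * n_target), axes(3 * n_target), rots(9 * n_target);
  std::vector<double> surf; // accepted cells' surface points
  surf.reserve((size_t)3 * n_surf * std::min(n_target, 4096));

  // cell-list over centers for neighbor prescreen
  const double amax = std::max(d1_max, d23) / 2.0;
  const double cell_sz = 2.0 * amax;
  int nb = std::max(1, (int)std::floor(box / cell_sz));
  double bsz = box / nb;
  std::vector<std::vector<int> > buckets((size_t)nb * nb * nb);
  auto bidx = [&](const double *c) {
    int ix = std::min(nb - 1, std::max(0, (int)((c[0] + box / 2) / bsz)));
    int iy = std::min(nb - 1, std::max(0, (int)((c[1] + box / 2) / bsz)));
    int iz = std::min(nb - 1, std::max(0, (int)((c[2] + box / 2) / bsz)));
    return (ix * nb + iy) * nb + iz;
  };

  int placed = 0;
  double attempts = 0;
  double cand_c[3], cand_a[3], cand_R[9];
  std::vector<double> cand_surf((size_t)3 * n_surf);

  while (placed < n_target && attempts < max_attempts) {
    attempts += 1;
    double d1 = rng.runif(d1_min, d1_max);
    cand_a[0] = d1 / 2.0; cand_a[1] = d23 / 2.0; cand_a[2] = d23 / 2.0;
    random_rotation(rng, cand_R);
    bool fits = true;
    for (int k = 0; k < 3; ++k) {
      double w = support_width(cand_R, cand_a, k);
      double half = box / 2.0 - w;
      if (half <= 0) { fits = false; break; }
      cand_c[k] = rng.runif(-half, half);
    }
    if (!fits) continue;

    // neighbor candidates
    bool overlap = false;
    int cx = (int)((cand_c[0] + box / 2) / bsz);
    int cy = (int)((cand_c[1] + box / 2) / bsz);
    int cz = (int)((cand_c[2] + box / 2) / bsz);
    bool surf_done = false;
    const double amin = d23 / 2.0;
    for (int ix = std::max(0, cx - 1); ix <= std::min(nb - 1, cx + 1) && !overlap; ++ix)
      for (int iy = std::max(0, cy - 1); iy <= std::min(nb - 1, cy + 1) && !overlap; ++iy)
        for (int iz = std::max(0, cz - 1); iz <= std::min(nb - 1, cz + 1) && !overlap; ++iz) {
          const std::vector<int> &bk = buckets[(size_t)(ix * nb + iy) * nb + iz];
          for (size_t q = 0; q < bk.size() && !overlap; ++q) {
            int j = bk[q];
            const double *cj = &centers[3 * j];
            double dx = cand_c[0] - cj[0], dy = cand_c[1] - cj[1], dz = cand_c[2] - cj[2];
            double dc2 = dx * dx + dy * dy + dz * dz;
            double rsum = cand_a[0] + axes[3 * j]; // bounding spheres (a[0] is max semi-axis)
            if (dc2 >= rsum * rsum) continue;
            double rmin = amin + axes[3 * j + 2];
            if (dc2 < rmin * rmin) { overlap = true; break; }
            if (!surf_done) {
              for (int s = 0; s < n_surf; ++s)
                to_world(cand_c, cand_R, cand_a, &usph[3 * s], &cand_surf[3 * s]);
              surf_done = true;
            }
            const double *aj = &axes[3 * j];
            const double *Rj = &rots[9 * j];
            for (int s = 0; s < n_surf; ++s) {
              if (enorm2(cj, Rj, aj, &cand_surf[3 * s]) < 1.0) { overlap = true; break; }
            }
            if (overlap) break;
            const double *sj = &surf[(size_t)3 * n_surf * j];
            for (int s = 0; s < n_surf; ++s) {
              if (enorm2(cand_c, cand_R, cand_a, &sj[3 * s]) < 1.0) { overlap = true; break; }
            }
          }
        }
    if (overlap) continue;

    if (!surf_done)
      for (int s = 0; s < n_surf; ++s)
        to_world(cand_c, cand_R, cand_a, &usph[3 * s], &cand_surf[3 * s]);
    for (int k = 0; k < 3; ++k) centers[3 * placed + k] = cand_c[k];
    for (int k = 0; k < 3; ++k) axes[3 * placed + k] = cand_a[k];
    for (int k = 0; k < 9; ++k) rots[9 * placed + k] = cand_R[k];
    surf.insert(surf.end(), cand_surf.begin(), cand_surf.end());
    buckets[bidx(cand_c)].push_back(placed);
    ++placed;
  }

  NumericMatrix C(placed, 3), A(placed, 3), RT(placed, 9);
  for (int i = 0; i < placed; ++i) {
    for (int k = 0; k < 3; ++k) { C(i, k) = centers[3 * i + k]; A(i, k) = axes[3 * i + k]; }
    for (int k = 0; k < 9; ++k) RT(i, k) = rots[9 * i + k];
  }
  return List::create(_["centers"] = C, _["axes"] = A, _["rot"] = RT,
                      _["placed"] = placed, _["attempts"] = attempts);
}

// Classify voxel centers: nucleus (1) / cytoplasm (2) by the center-point
// test in each cell's rotated frame; unmatched voxels stay intercellular (0).
// [[Rcpp::export(".cpp_voxelize")]]
List cpp_voxelize(NumericMatrix centers, NumericMatrix axes, NumericMatrix rot,
                  NumericVector nucleus_scale, double box, double vs) {
  int m = (int)std::lround(box / vs);
  size_t nvox = (size_t)m * m * m;
  IntegerVector type((R_xlen_t)nvox), cellid((R_xlen_t)nvox);
  double x0 = -(box / 2.0 - vs / 2.0);
  int ncell = centers.nrow();
  for (int ci = 0; ci < ncell; ++ci) {
    double c[3] = { centers(ci, 0), centers(ci, 1), centers(ci, 2) };
    double a[3] = { axes(ci, 0), axes(ci, 1), axes(ci, 2) };
    double R[9]; for (int k = 0; k < 9; ++k) R[k] = rot(ci, k);
    double ns = nucleus_scale[ci];
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double w = support_width(R, a, k);
      lo[k] = std::max(0, (int)std::ceil((c[k] - w - x0) / vs - 1e-9));
      hi[k] = std::min(m - 1, (int)std::floor((c[k] + w - x0) / vs + 1e-9));
    }
    double p[3];
    for (int i = lo[0]; i <= hi[0]; ++i) {
      p[0] = x0 + vs * i;
      for (int j = lo[1]; j <= hi[1]; ++j) {
        p[1] = x0 + vs * j;
        for (int k = lo[2]; k <= hi[2]; ++k) {
          p[2] = x0 + vs * k;
          double e2 = enorm2(c, R, a, p);
          if (e2 <= 1.0) {
            // arrays stored with i fastest (x), matching R array dim (m, m, m)
            size_t idx = (size_t)i + (size_t)m * ((size_t)j + (size_t)m * k);
            type[idx] = (e2 <= ns * ns) ? 1 : 2;
            cellid[idx] = ci + 1;
          }
        }
      }
    }
  }
  return List::create(_["type"] = type, _["cell"] = cellid, _["m"] = m);
}
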