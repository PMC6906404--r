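#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <cmath>
#include "rng.h"

using namespace Rcpp;
using radcell::Rng;
using radcell::mix_seed;

// ---------------------------------------------------------------------------
// shared small structures

struct Grid {
  const int *type;
  const int *cell;
  int m;
  double box, vs;
  // voxel index of a position (or -1 if outside the box)
  inline long vox(double x, double y, double z) const {
    int i = (int)std::floor((x + box / 2.0) / vs);
    int j = (int)std::floor((y + box / 2.0) / vs);
    int k = (int)std::floor((z + box / 2.0) / vs);
    if (i < 0 || j < 0 || k < 0 || i >= m || j >= m || k >= m) return -1;
    return (long)i + (long)m * ((long)j + (long)m * k);
  }
  inline bool nucleus_of(double x, double y, double z, int id) const {
    long v = vox(x, y, z);
    return v >= 0 && type[v] == 1 && cell[v] == id;
  }
};

struct CellGeom { double c[3], a[3], R[9], ns; int id; };

struct Model {
  double fluence;        // tracks / um^2 / Gy
  double emean, emin;    // eV
  double oh_ratio;
  double oh_sigma;       // per-axis, um
  double jitter_sigma;   // per-axis, um (direct events)
  double cluster_density; // clusters / um of chord
  double sparse_mean;    // mean direct events per sparse cluster (geometric)
  int sparse_cap;        // truncation of the sparse cluster size
  double p_dense, dense_min, dense_extra;
};

struct DamageParams {
  double capture, chain_r;     // um
  double f_sugar_d, f_sugar_oh;
  int merge_gap, cplx_thresh;
  bool opposite;
};

static Model model_from_list(List m) {
  Model M;
  M.fluence = as<double>(m["fluence_per_um2_per_Gy"]);
  M.emean = as<double>(m["mean_deposit_eV"]);
  M.emin = as<double>(m["energy_threshold_eV"]);
  M.oh_ratio = as<double>(m["oh_per_direct_ratio"]);
  M.oh_sigma = as<double>(m["oh_sigma_um"]);
  M.jitter_sigma = as<double>(m["cluster_radius_um"]);
  M.cluster_density = as<double>(m["cluster_density_per_um"]);
  M.sparse_mean = as<double>(m["cluster_mean_direct"]);
  M.sparse_cap = as<int>(m["cluster_cap_direct"]);
  M.p_dense = as<double>(m["p_dense"]);
  M.dense_min = as<double>(m["dense_min"]);
  M.dense_extra = as<double>(m["dense_extra_mean"]);
  return M;
}

static DamageParams dparams_from_list(List d) {
  DamageParams P;
  P.capture = as<double>(d["capture_radius_um"]);
  P.chain_r = as<double>(d["chain_radius_um"]);
  P.f_sugar_d = as<double>(d["sugar_hit_fraction_direct"]);
  P.f_sugar_oh = as<double>(d["sugar_hit_fraction_oh"]);
  P.merge_gap = as<int>(d["merge_gap_bp"]);
  P.cplx_thresh = as<int>(d["cdsb_elementary_threshold"]);
  P.opposite = as<bool>(d["opposite_strand_rule"]);
  return P;
}

// ---------------------------------------------------------------------------
// track / event generation for one nucleus

struct Events {
  std::vector<double> x, y, z, e;
  std::vector<int> kind, track; // kind: 0 direct, 1 indirect
  void clear() { x.clear(); y.clear(); z.clear(); e.clear(); kind.clear(); track.clear(); }
  size_t n() const { return x.size(); }
};

static void ortho_basis(const double *u, double *b1, double *b2) {
  if (std::fabs(u[0]) < 0.9) { b1[0] = 0; b1[1] = -u[2]; b1[2] = u[1]; }
  else { b1[0] = -u[1]; b1[1] = u[0]; b1[2] = 0; }
  double n = std::sqrt(b1[0] * b1[0] + b1[1] * b1[1] + b1[2] * b1[2]);
  for (int k = 0; k < 3; ++k) b1[k] /= n;
  b2[0] = u[1] * b1[2] - u[2] * b1[1];
  b2[1] = u[2] * b1[0] - u[0] * b1[2];
  b2[2] = u[0] * b1[1] - u[1] * b1[0];
}

// Isotropic uniform random chords through the bounding sphere of the nucleus;
// interaction clusters Poisson-spaced along each chord, retained only where
// the position falls in a nucleus voxel of the owning cell.
static void generate_cell(Rng &rng, const CellGeom &g, const Grid &grid,
                          const Model &M, double dose, Events &ev,
                          double &energy_eV, int &n_tracks,
                          double *voxel_energy) {
  ev.clear();
  energy_eV = 0.0;
  double na_max = g.ns * std::max(g.a[0], std::max(g.a[1], g.a[2]));
  double rb = na_max + grid.vs;
  double mean_tracks = M.fluence * dose * M_PI * rb * rb;
  n_tracks = rng.rpois(mean_tracks);
  double u[3], b1[3], b2[3], p0[3];
  for (int t = 0; t < n_tracks; ++t) {
    // uniform direction
    double nn;
    do {
      for (int k = 0; k < 3; ++k) u[k] = rng.rnorm();
      nn = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    } while (nn < 1e-12);
    for (int k = 0; k < 3; ++k) u[k] /= nn;
    ortho_basis(u, b1, b2);
    double rr = rb * std::sqrt(rng.u01());
    double th = rng.runif(0, 2 * M_PI);
    for (int k = 0; k < 3; ++k)
      p0[k] = g.c[k] + rr * std::cos(th) * b1[k] + rr * std::sin(th) * b2[k];
    double h = std::sqrt(std::max(0.0, rb * rb - rr * rr));
    int n_cl = rng.rpois(M.cluster_density * 2.0 * h);
    for (int cl = 0; cl < n_cl; ++cl) {
      double s = rng.runif(-h, h);
      double cx = p0[0] + s * u[0], cy = p0[1] + s * u[1], cz = p0[2] + s * u[2];
      if (!grid.nucleus_of(cx, cy, cz, g.id)) continue;
      int k_dir;
      if (M.p_dense > 0.0 && rng.u01() < M.p_dense) {
        k_dir = (int)M.dense_min + rng.rpois(M.dense_extra);
      } else {
        k_dir = rng.rgeom1(1.0 / M.sparse_mean);
        if (k_dir > M.sparse_cap) k_dir = M.sparse_cap;
      }
      for (int q = 0; q < k_dir; ++q) {
        double px = cx + M.jitter_sigma * rng.rnorm();
        double py = cy + M.jitter_sigma * rng.rnorm();
        double pz = cz + M.jitter_sigma * rng.rnorm();
        double en = M.emin + rng.rexp(M.emean - M.emin);
        if (!grid.nucleus_of(px, py, pz, g.id)) continue;
        ev.x.push_back(px); ev.y.push_back(py); ev.z.push_back(pz);
        ev.e.push_back(en); ev.kind.push_back(0); ev.track.push_back(t);
        energy_eV += en;
        if (voxel_energy) voxel_energy[grid.vox(px, py, pz)] += en;
      }
      int n_oh = rng.rpois(M.oh_ratio * k_dir);
      for (int q = 0; q < n_oh; ++q) {
        double px = cx + M.oh_sigma * rng.rnorm();
        double py = cy + M.oh_sigma * rng.rnorm();
        double pz = cz + M.oh_sigma * rng.rnorm();
        if (!grid.nucleus_of(px, py, pz, g.id)) continue;
        ev.x.push_back(px); ev.y.push_back(py); ev.z.push_back(pz);
        ev.e.push_back(NA_REAL); ev.kind.push_back(1); ev.track.push_back(t);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// clustering into 10-bp segments with chain bookkeeping

struct Seg {
  double cx, cy, cz;
  int n;            // events joined
  int chain, cpos;  // chain id (0-based) and genomic offset within chain
  uint32_t occ;     // 20 sites: slot = (strand-1)*10 + (bp-1)
  int8_t moiety[20];  // 1 sugar, 2 base
  int8_t lesion[20];  // 1 strand break, 2 modified sugar, 3 modified base
  uint8_t cnt[20];    // collapsed events per site
  std::vector<int> tracks;
};

struct SegStore {
  std::vector<Seg> segs;
  std::vector<int> chain_maxpos;
  std::vector<int> ev_seg; // segment of each event (0-based)
};

static inline uint64_t hkey(int ix, int iy, int iz) {
  return ((uint64_t)(uint32_t)ix * 73856093ULL) ^
         ((uint64_t)(uint32_t)iy * 19349663ULL) ^
         ((uint64_t)(uint32_t)iz * 83492791ULL);
}

// Greedy single-linkage clustering: an event joins the nearest existing
// segment whose centroid is within the capture radius, otherwise it seeds a
// new segment. A new segment chains to the nearest segment within the chain
// radius (consecutive genomic offsets), otherwise it starts a new chain.
static void cluster_cell(Rng &rng, const Events &ev, const DamageParams &P,
                         SegStore &S) {
  size_t n = ev.n();
  S.segs.clear(); S.chain_maxpos.clear();
  S.ev_seg.assign(n, -1);
  S.segs.reserve(n / 2 + 8);
  std::unordered_map<uint64_t, std::vector<int> > hash;
  hash.reserve(n);
  const double cell_sz = P.chain_r;
  const double cap2 = P.capture * P.capture;
  const double chain2 = P.chain_r * P.chain_r;
  for (size_t i = 0; i < n; ++i) {
    double x = ev.x[i], y = ev.y[i], z = ev.z[i];
    int ix = (int)std::floor(x / cell_sz), iy = (int)std::floor(y / cell_sz),
        iz = (int)std::floor(z / cell_sz);
    int best_cap = -1, best_chain = -1;
    double dcap = cap2, dchain = chain2;
    for (int a = ix - 1; a <= ix + 1; ++a)
      for (int b = iy - 1; b <= iy + 1; ++b)
        for (int c = iz - 1; c <= iz + 1; ++c) {
          std::unordered_map<uint64_t, std::vector<int> >::iterator it =
              hash.find(hkey(a, b, c));
          if (it == hash.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            const Seg &sg = S.segs[v[q]];
            double dx = sg.cx - x, dy = sg.cy - y, dz = sg.cz - z;
            double d2 = dx * dx + dy * dy + dz * dz;
            if (d2 < dcap) { dcap = d2; best_cap = v[q]; }
            if (d2 < dchain) { dchain = d2; best_chain = v[q]; }
          }
        }
    int si;
    if (best_cap >= 0) {
      si = best_cap;
      Seg &sg = S.segs[si];
      sg.cx += (x - sg.cx) / (sg.n + 1);
      sg.cy += (y - sg.cy) / (sg.n + 1);
      sg.cz += (z - sg.cz) / (sg.n + 1);
      sg.n += 1;
    } else {
      Seg sg;
      sg.cx = x; sg.cy = y; sg.cz = z; sg.n = 1; sg.occ = 0;
      std::fill(sg.moiety, sg.moiety + 20, 0);
      std::fill(sg.lesion, sg.lesion + 20, 0);
      std::fill(sg.cnt, sg.cnt + 20, 0);
      if (best_chain >= 0) {
        sg.chain = S.segs[best_chain].chain;
        sg.cpos = ++S.chain_maxpos[sg.chain];
      } else {
        sg.chain = (int)S.chain_maxpos.size();
        sg.cpos = 0;
        S.chain_maxpos.push_back(0);
      }
      si = (int)S.segs.size();
      S.segs.push_back(sg);
      hash[hkey(ix, iy, iz)].push_back(si);
    }
    S.ev_seg[i] = si;
    Seg &sg = S.segs[si];
    // site assignment: bp, strand, moiety; duplicate (bp, strand) collapses
    int bp = rng.rint(10);
    int strand = rng.u01() < 0.5 ? 0 : 1;
    double fs = ev.kind[i] == 0 ? P.f_sugar_d : P.f_sugar_oh;
    int moi = rng.u01() < fs ? 1 : 2;
    int slot = strand * 10 + bp;
    if (!(sg.occ & (1u << slot))) {
      sg.occ |= (1u << slot);
      sg.moiety[slot] = (int8_t)moi;
    }
    if (sg.cnt[slot] < 255) sg.cnt[slot]++;
    int tr = ev.track[i];
    bool seen = false;
    for (size_t q = 0; q < sg.tracks.size(); ++q)
      if (sg.tracks[q] == tr) { seen = true; break; }
    if (!seen) sg.tracks.push_back(tr);
  }
}

// pO2-resolved lesion conversion; one uniform draw per sugar site, in
// segment-creation / slot order (the documented stream order).
static void lesions_cell(Rng &rng, SegStore &S, double p_break) {
  for (size_t i = 0; i < S.segs.size(); ++i) {
    Seg &sg = S.segs[i];
    for (int slot = 0; slot < 20; ++slot) {
      if (!(sg.occ & (1u << slot))) continue;
      if (sg.moiety[slot] == 1)
        sg.lesion[slot] = rng.u01() < p_break ? 1 : 2;
      else
        sg.lesion[slot] = 3;
    }
  }
}

// ---------------------------------------------------------------------------
// DSB calling with the merge / multiplicity rule

struct Dsb {
  double x, y, z;
  int nsb, nelem, mult;
  bool cplx;
  std::vector<int> tracks;
};

static inline int popcount20(uint32_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// one damaged base pair of a chain (either strand)
struct BpDmg {
  int bp;        // absolute genomic position: cpos*10 + (1..10)
  int nsites;    // lesioned sites at this bp (1 or 2)
  int nbrk;      // strand-break sites at this bp
  int seg;       // a segment holding this bp (for centroid/tracks)
};

// DSB calling per chain:
//  * a segment with >= 2 strand breaks (opposite strands by default) is a
//    DSB candidate;
//  * candidates separated by fewer than merge_gap undamaged base pairs merge
//    (multiplicity = merged candidates);
//  * a DSB's elementary damages are all lesions of its contiguous damaged
//    region: damaged base pairs connected to its breaks through undamaged
//    runs shorter than merge_gap (the same genomic window notion the merge
//    rule uses), on either strand.
static void dsbs_cell(const SegStore &S, const DamageParams &P,
                      std::vector<Dsb> &out) {
  out.clear();
  int nchain = (int)S.chain_maxpos.size();
  std::vector<std::vector<int> > bychain(nchain);
  for (size_t i = 0; i < S.segs.size(); ++i)
    bychain[S.segs[i].chain].push_back((int)i);

  std::vector<BpDmg> dmg;
  for (int ch = 0; ch < nchain; ++ch) {
    std::vector<int> &segs = bychain[ch];
    if (segs.empty()) continue;
    std::sort(segs.begin(), segs.end(), [&](int a, int b) {
      return S.segs[a].cpos < S.segs[b].cpos;
    });
    struct Cand { int seg, minbrk, maxbrk, nsb; };
    std::vector<Cand> cands;
    dmg.clear();
    for (size_t q = 0; q < segs.size(); ++q) {
      const Seg &sg = S.segs[segs[q]];
      int s1 = 0, s2 = 0, mn = 1 << 30, mx = -1;
      for (int bp = 0; bp < 10; ++bp) {
        int ns = 0, nb = 0;
        for (int str = 0; str < 2; ++str) {
          int slot = str * 10 + bp;
          if (sg.occ & (1u << slot)) {
            ++ns;
            if (sg.lesion[slot] == 1) ++nb;
          }
        }
        if (ns) {
          BpDmg b;
          b.bp = sg.cpos * 10 + bp + 1;
          b.nsites = ns; b.nbrk = nb; b.seg = segs[q];
          dmg.push_back(b);
        }
      }
      for (int slot = 0; slot < 20; ++slot) {
        if (sg.lesion[slot] != 1) continue;
        if (slot < 10) ++s1; else ++s2;
        int abs_bp = sg.cpos * 10 + (slot % 10) + 1;
        mn = std::min(mn, abs_bp); mx = std::max(mx, abs_bp);
      }
      bool cand = P.opposite ? (s1 > 0 && s2 > 0) : (s1 + s2 >= 2);
      if (cand) {
        Cand c; c.seg = segs[q]; c.minbrk = mn; c.maxbrk = mx; c.nsb = s1 + s2;
        cands.push_back(c);
      }
    }
    if (cands.empty()) continue;
    // dmg holds distinct bps sorted by position (segments have distinct cpos)
    std::sort(dmg.begin(), dmg.end(),
              [](const BpDmg &a, const BpDmg &b) { return a.bp < b.bp; });

    // merge scan over candidates ordered along the chain
    size_t i = 0;
    while (i < cands.size()) {
      int mult = 1;
      int gmin = cands[i].minbrk, gmax = cands[i].maxbrk;
      size_t j = i + 1;
      while (j < cands.size()) {
        int span = cands[j].minbrk - gmax - 1; // bp strictly between
        long ndmg = 0;
        for (size_t q = 0; q < dmg.size(); ++q)
          if (dmg[q].bp > gmax && dmg[q].bp < cands[j].minbrk) ++ndmg;
        int undam = span - (int)ndmg;
        if (undam < P.merge_gap) {
          ++mult;
          gmax = std::max(gmax, cands[j].maxbrk);
          ++j;
        } else break;
      }
      // attribution region: expand [gmin, gmax] through damaged bps with
      // undamaged runs < merge_gap on both sides
      size_t lo = 0;
      while (lo < dmg.size() && dmg[lo].bp < gmin) ++lo;
      size_t hi = lo;
      while (hi < dmg.size() && dmg[hi].bp <= gmax) ++hi;
      // hi is one past the region; expand left
      while (lo > 0) {
        int gap = dmg[lo].bp - dmg[lo - 1].bp - 1;
        if (gap < P.merge_gap) --lo; else break;
      }
      while (hi < dmg.size()) {
        int gap = dmg[hi].bp - dmg[hi - 1].bp - 1;
        if (gap < P.merge_gap) ++hi; else break;
      }
      Dsb d; d.x = d.y = d.z = 0; d.nsb = 0; d.nelem = 0;
      d.mult = mult;
      for (size_t q = lo; q < hi; ++q) {
        const BpDmg &b = dmg[q];
        d.nelem += b.nsites;
        d.nsb += b.nbrk;
        if (b.nbrk) {
          const Seg &sg = S.segs[b.seg];
          d.x += sg.cx * b.nbrk; d.y += sg.cy * b.nbrk; d.z += sg.cz * b.nbrk;
        }
        const Seg &sg = S.segs[b.seg];
        for (size_t t = 0; t < sg.tracks.size(); ++t)
          d.tracks.push_back(sg.tracks[t]);
      }
      d.x /= d.nsb; d.y /= d.nsb; d.z /= d.nsb;
      std::sort(d.tracks.begin(), d.tracks.end());
      d.tracks.erase(std::unique(d.tracks.begin(), d.tracks.end()), d.tracks.end());
      d.cplx = d.nelem > P.cplx_thresh;
      out.push_back(d);
      i = j;
    }
  }
}

static void thin_cells(Rng &rng, std::vector<Dsb> &dsbs, double fraction,
                       std::vector<Dsb> &kept) {
  kept.clear();
  for (size_t i = 0; i < dsbs.size(); ++i)
    if (rng.u01() < fraction) kept.push_back(dsbs[i]);
}

// ---------------------------------------------------------------------------
// exported kernels

// [[Rcpp::export(".cpp_mix_seed")]]
double cpp_mix_seed(double seed, double a, double b) { return mix_seed(seed, a, b); }

// [[Rcpp::export(".cpp_u01")]]
NumericVector cpp_u01(int n, double seed) {
  Rng rng(seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.u01();
  return out;
}

// [[Rcpp::export(".cpp_rnorm3_norm")]]
NumericVector cpp_rnorm3_norm(int n, double sigma, double seed) {
  Rng rng(seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double a = rng.rnorm(), b = rng.rnorm(), c = rng.rnorm();
    out[i] = sigma * std::sqrt(a * a + b * b + c * c);
  }
  return out;
}

static std::vector<CellGeom> geoms_from(NumericMatrix centers, NumericMatrix axes,
                                        NumericMatrix rot, NumericVector ns,
                                        IntegerVector ids) {
  std::vector<CellGeom> g(ids.size());
  for (int i = 0; i < ids.size(); ++i) {
    int row = ids[i] - 1;
    for (int k = 0; k < 3; ++k) { g[i].c[k] = centers(row, k); g[i].a[k] = axes(row, k); }
    for (int k = 0; k < 9; ++k) g[i].R[k] = rot(row, k);
    g[i].ns = ns[row];
    g[i].id = ids[i];
  }
  return g;
}

// [[Rcpp::export(".cpp_generate_events")]]
List cpp_generate_events(IntegerVector vtype, IntegerVector vcell, int m,
                         double box, double vs, NumericMatrix centers,
                         NumericMatrix axes, NumericMatrix rot,
                         NumericVector nucleus_scale, IntegerVector cell_ids,
                         NumericVector nuc_vox, double dose, List model,
                         double seed, bool voxel_energy) {
  Grid grid; grid.type = INTEGER(vtype); grid.cell = INTEGER(vcell);
  grid.m = m; grid.box = box; grid.vs = vs;
  Model M = model_from_list(model);
  std::vector<CellGeom> geoms = geoms_from(centers, axes, rot, nucleus_scale, cell_ids);

  NumericVector venergy;
  double *vptr = NULL;
  if (voxel_energy) { venergy = NumericVector((R_xlen_t)m * m * m); vptr = REAL(venergy); }

  std::vector<double> X, Y, Z, E;
  std::vector<int> K, T, C;
  NumericVector dose_out(geoms.size());
  IntegerVector ntracks(geoms.size());
  Events ev;
  const double eV_to_J = 1.602176634e-19;
  for (size_t i = 0; i < geoms.size(); ++i) {
    Rng rng(mix_seed(seed, geoms[i].id, 0));
    double en; int nt;
    generate_cell(rng, geoms[i], grid, M, dose, ev, en, nt, vptr);
    double mass_kg = nuc_vox[i] * 1e-15; // um^3 at 1 g/cm^3
    dose_out[i] = nuc_vox[i] > 0 ? en * eV_to_J / mass_kg : 0.0;
    ntracks[i] = nt;
    for (size_t q = 0; q < ev.n(); ++q) {
      X.push_back(ev.x[q]); Y.push_back(ev.y[q]); Z.push_back(ev.z[q]);
      E.push_back(ev.e[q]); K.push_back(ev.kind[q]); T.push_back(ev.track[q]);
      C.push_back(geoms[i].id);
    }
  }
  List out = List::create(
      _["cell_id"] = wrap(C), _["track_id"] = wrap(T), _["kind"] = wrap(K),
      _["x_um"] = wrap(X), _["y_um"] = wrap(Y), _["z_um"] = wrap(Z),
      _["energy_eV"] = wrap(E), _["nucleus_dose_Gy"] = dose_out,
      _["n_tracks"] = ntracks);
  if (voxel_energy) out["voxel_energy_eV"] = venergy;
  return out;
}

// [[Rcpp::export(".cpp_cluster_events")]]
List cpp_cluster_events(NumericVector x, NumericVector y, NumericVector z,
                        IntegerVector kind, IntegerVector track, List dparams,
                        double seed) {
  DamageParams P = dparams_from_list(dparams);
  Events ev;
  int n = x.size();
  ev.x.assign(x.begin(), x.end());
  ev.y.assign(y.begin(), y.end());
  ev.z.assign(z.begin(), z.end());
  ev.kind.assign(kind.begin(), kind.end());
  ev.track.assign(track.begin(), track.end());
  ev.e.assign(n, 0.0);
  Rng rng(seed);
  SegStore S;
  cluster_cell(rng, ev, P, S);

  // site table in segment-creation / slot order (the lesion stream order)
  std::vector<int> s_seg, s_chain, s_cpos, s_bp, s_strand, s_moi, s_cnt;
  std::vector<double> s_x, s_y, s_z;
  for (size_t i = 0; i < S.segs.size(); ++i) {
    const Seg &sg = S.segs[i];
    for (int slot = 0; slot < 20; ++slot) {
      if (!(sg.occ & (1u << slot))) continue;
      s_seg.push_back((int)i + 1);
      s_chain.push_back(sg.chain + 1);
      s_cpos.push_back(sg.cpos);
      s_bp.push_back(slot % 10 + 1);
      s_strand.push_back(slot / 10 + 1);
      s_moi.push_back(sg.moiety[slot]);
      s_cnt.push_back(sg.cnt[slot]);
      s_x.push_back(sg.cx); s_y.push_back(sg.cy); s_z.push_back(sg.cz);
    }
  }
  CharacterVector seg_tracks(S.segs.size());
  IntegerVector seg_n(S.segs.size());
  for (size_t i = 0; i < S.segs.size(); ++i) {
    std::vector<int> tr = S.segs[i].tracks;
    std::sort(tr.begin(), tr.end());
    std::string s;
    for (size_t q = 0; q < tr.size(); ++q) {
      if (q) s += ";";
      s += std::to_string(tr[q]);
    }
    seg_tracks[i] = s;
    seg_n[i] = S.segs[i].n;
  }
  return List::create(
      _["segment"] = wrap(s_seg), _["chain"] = wrap(s_chain),
      _["chain_pos"] = wrap(s_cpos), _["seg_x"] = wrap(s_x),
      _["seg_y"] = wrap(s_y), _["seg_z"] = wrap(s_z), _["bp"] = wrap(s_bp),
      _["strand"] = wrap(s_strand), _["moiety"] = wrap(s_moi),
      _["n_events"] = wrap(s_cnt), _["event_segment"] = wrap(S.ev_seg),
      _["segment_tracks"] = seg_tracks, _["segment_n_events"] = seg_n);
}

// [[Rcpp::export(".cpp_lesions")]]
IntegerVector cpp_lesions(IntegerVector moiety, double p_break, double seed) {
  Rng rng(seed);
  IntegerVector out(moiety.size());
  for (int i = 0; i < moiety.size(); ++i) {
    if (moiety[i] == 1)
      out[i] = rng.u01() < p_break ? 1 : 2;
    else
      out[i] = 3;
  }
  return out;
}

// Fused per-cell pipeline: generate -> cluster -> lesions -> DSBs -> thin.
// Stage seeds are mix_seed(seed, cell_id, stage) with stages 0..3, so the
// modular operations reproduce any cell exactly.
// [[Rcpp::export(".cpp_simulate_damage_cells")]]
List cpp_simulate_damage_cells(IntegerVector vtype, IntegerVector vcell, int m,
                               double box, double vs, NumericMatrix centers,
                               NumericMatrix axes, NumericMatrix rot,
                               NumericVector nucleus_scale,
                               IntegerVector cell_ids, NumericVector nuc_vox,
                               double dose, List model, List dparams,
                               NumericVector p_break, double dna_fraction,
                               bool include_indirect, bool collect_details,
                               double seed, double track_seed) {
  Grid grid; grid.type = INTEGER(vtype); grid.cell = INTEGER(vcell);
  grid.m = m; grid.box = box; grid.vs = vs;
  Model M = model_from_list(model);
  DamageParams P = dparams_from_list(dparams);
  std::vector<CellGeom> geoms = geoms_from(centers, axes, rot, nucleus_scale, cell_ids);

  int nc = (int)geoms.size();
  IntegerVector n_dsb(nc), n_cdsb(nc), n_dsb_raw(nc), n_cdsb_raw(nc),
      n_direct(nc), n_indirect(nc), n_tracks_out(nc);
  NumericVector dose_out(nc);
  std::vector<int> cd_cell; std::vector<double> cd_x, cd_y, cd_z;
  std::vector<std::string> cd_tracks;
  std::vector<int> dt_cell, dt_nsb, dt_nelem, dt_mult, dt_cplx;

  Events ev, evd;
  SegStore S;
  std::vector<Dsb> dsbs, kept;
  const double eV_to_J = 1.602176634e-19;

  for (int i = 0; i < nc; ++i) {
    const CellGeom &g = geoms[i];
    {
      Rng rng(mix_seed(track_seed, g.id, 0));
      double en; int nt;
      generate_cell(rng, g, grid, M, dose, ev, en, nt, NULL);
      dose_out[i] = nuc_vox[i] > 0 ? en * eV_to_J / (nuc_vox[i] * 1e-15) : 0.0;
      n_tracks_out[i] = nt;
    }
    int nd = 0, ni = 0;
    for (size_t q = 0; q < ev.n(); ++q) (ev.kind[q] == 0 ? nd : ni)++;
    n_direct[i] = nd; n_indirect[i] = ni;
    const Events *use = &ev;
    if (!include_indirect) {
      evd.clear();
      for (size_t q = 0; q < ev.n(); ++q) {
        if (ev.kind[q] != 0) continue;
        evd.x.push_back(ev.x[q]); evd.y.push_back(ev.y[q]); evd.z.push_back(ev.z[q]);
        evd.e.push_back(ev.e[q]); evd.kind.push_back(0); evd.track.push_back(ev.track[q]);
      }
      use = &evd;
    }
    {
      Rng rng(mix_seed(seed, g.id, 1));
      cluster_cell(rng, *use, P, S);
    }
    {
      Rng rng(mix_seed(seed, g.id, 2));
      lesions_cell(rng, S, p_break[i]);
    }
    dsbs_cell(S, P, dsbs);
    n_dsb_raw[i] = (int)dsbs.size();
    int craw = 0;
    for (size_t q = 0; q < dsbs.size(); ++q) if (dsbs[q].cplx) ++craw;
    n_cdsb_raw[i] = craw;
    {
      Rng rng(mix_seed(seed, g.id, 3));
      thin_cells(rng, dsbs, dna_fraction, kept);
    }
    n_dsb[i] = (int)kept.size();
    int ck = 0;
    for (size_t q = 0; q < kept.size(); ++q) {
      const Dsb &d = kept[q];
      if (d.cplx) {
        ++ck;
        cd_cell.push_back(g.id);
        cd_x.push_back(d.x); cd_y.push_back(d.y); cd_z.push_back(d.z);
        std::string s;
        for (size_t t = 0; t < d.tracks.size(); ++t) {
          if (t) s += ";";
          s += std::to_string(d.tracks[t]);
        }
        cd_tracks.push_back(s);
      }
      if (collect_details) {
        dt_cell.push_back(g.id);
        dt_nsb.push_back(d.nsb); dt_nelem.push_back(d.nelem);
        dt_mult.push_back(d.mult); dt_cplx.push_back(d.cplx ? 1 : 0);
      }
    }
    n_cdsb[i] = ck;
  }

  List out = List::create(
      _["cell_id"] = cell_ids, _["n_dsb"] = n_dsb, _["n_cdsb"] = n_cdsb,
      _["n_dsb_raw"] = n_dsb_raw, _["n_cdsb_raw"] = n_cdsb_raw,
      _["nucleus_dose_Gy"] = dose_out, _["n_direct"] = n_direct,
      _["n_indirect"] = n_indirect, _["n_tracks"] = n_tracks_out,
      _["cdsb_cell"] = wrap(cd_cell), _["cdsb_x"] = wrap(cd_x),
      _["cdsb_y"] = wrap(cd_y), _["cdsb_z"] = wrap(cd_z),
      _["cdsb_tracks"] = wrap(cd_tracks));
  if (collect_details) {
    out["dsb_cell"] = wrap(dt_cell);
    out["dsb_nsb"] = wrap(dt_nsb);
    out["dsb_nelem"] = wrap(dt_nelem);
    out["dsb_mult"] = wrap(dt_mult);
    out["dsb_cplx"] = wrap(dt_cplx);
  }
  return out;
}
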