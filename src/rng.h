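#ifndef RADCELL_RNG_H
#define RADCELL_RNG_H

#include <cstdint>
#include <cmath>

// Self-contained counter-seeded RNG (splitmix64 seeding + xoshiro256++).
// The package does not use R's global RNG inside compiled kernels: every
// kernel receives an explicit seed so that any (cell, dose, condition)
// stream can be replayed in isolation.

namespace radcell {

inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Deterministic child-seed derivation; folded to 31 bits so the value is
// exactly representable as an R integer/double and reusable as a seed.
inline double mix_seed(double seed, double a, double b) {
  uint64_t s = (uint64_t)(int64_t)seed;
  uint64_t h = s;
  splitmix64(h);
  h ^= (uint64_t)(int64_t)a + 0x9E3779B97F4A7C15ULL;
  splitmix64(h);
  h ^= (uint64_t)(int64_t)b + 0xD1B54A32D192ED03ULL;
  uint64_t z = splitmix64(h);
  return (double)(z >> 33); // < 2^31
}

class Rng {
public:
  explicit Rng(double seed) {
    uint64_t s = (uint64_t)(int64_t)seed;
    for (int i = 0; i < 4; ++i) state_[i] = splitmix64(s);
    have_spare_ = false;
  }

  // uniform in (0, 1)
  double u01() {
    uint64_t x = next();
    return ((x >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  double runif(double a, double b) { return a + (b - a) * u01(); }

  double rnorm() {
    if (have_spare_) { have_spare_ = false; return spare_; }
    double u, v, s;
    do {
      u = 2.0 * u01() - 1.0;
      v = 2.0 * u01() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare_ = v * m;
    have_spare_ = true;
    return u * m;
  }

  double rexp(double mean) { return -mean * std::log(u01()); }

  // exact Poisson: Knuth below 30, additive split above (Poisson additivity)
  int rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda > 30.0) {
      double half = lambda * 0.5;
      return rpois(half) + rpois(lambda - half);
    }
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { ++k; p *= u01(); } while (p > L);
    return k - 1;
  }

  // geometric on {1, 2, ...} with success probability p (mean 1/p)
  int rgeom1(double p) {
    if (p >= 1.0) return 1;
    return 1 + (int)std::floor(std::log(u01()) / std::log1p(-p));
  }

  // integer in [0, n)
  int rint(int n) {
    int k = (int)(u01() * n);
    return k >= n ? n - 1 : k;
  }

private:
  uint64_t state_[4];
  bool have_spare_;
  double spare_;

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(state_[0] + state_[3], 23) + state_[0];
    uint64_t t = state_[1] << 17;
    state_[2] ^= state_[0];
    state_[3] ^= state_[1];
    state_[1] ^= state_[2];
    state_[0] ^= state_[3];
    state_[2] ^= t;
    state_[3] = rotl(state_[3], 45);
    return result;
  }
};

} // namespace radcell

#endif
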