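#ifndef ALN_RNG_H
#define ALN_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained RNG (xoshiro256++ seeded via splitmix64) with a
// Box-Muller normal generator. Used instead of std::normal_distribution so
// that a given stream seed yields the same draws on any standards-conforming
// compiler, which the simulation determinism contract relies on.
struct AlnRng {
  uint64_t s[4];
  double cached;
  bool has_cached;

  explicit AlnRng(uint64_t seed = 1) { init(seed); }

  void init(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t x = z;
      x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
      x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
      s[i] = x ^ (x >> 31);
    }
    has_cached = false;
    cached = 0.0;
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1]
  inline double runif_pos() {
    return ((next() >> 11) + 1.0) * (1.0 / 9007199254740993.0);
  }

  inline double rnorm() {
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    double u1 = runif_pos();
    double u2 = runif_pos();
    double rad = std::sqrt(-2.0 * std::log(u1));
    double ang = 6.283185307179586476925286766559 * u2;
    cached = rad * std::sin(ang);
    has_cached = true;
    return rad * std::cos(ang);
  }
};

#endif
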