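#ifndef CELLFLOW_RNG_H
#define CELLFLOW_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256++ seeded through splitmix64; normal deviates by polar
// Box-Muller with one cached spare.  Single stream, single thread:
// runs are bit-reproducible for a given seed.
struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; i++) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

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

  // uniform in (0,1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

#endif
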