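#ifndef HZ_RNG_H
#define HZ_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained generator (splitmix64 core) so compiled hot loops do
// not round-trip through R's RNG state. Seeded from a user-visible integer.
struct HZRng {
  uint64_t s;
  bool has_cached;
  double cached;

  explicit HZRng(uint64_t seed)
      : s(seed ? seed : 0x9E3779B97F4A7C15ULL), has_cached(false), cached(0.0) {}

  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  // uniform on [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }

  // standard normal via Box-Muller (cached pair)
  double norm() {
    if (has_cached) {
      has_cached = false;
      return cached;
    }
    double u1;
    do {
      u1 = unif();
    } while (u1 <= 0.0);
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    cached = r * std::sin(a);
    has_cached = true;
    return r * std::cos(a);
  }

  double expo() {
    double u;
    do {
      u = unif();
    } while (u <= 0.0);
    return -std::log(u);
  }

  // Poisson by inversion of the product of uniforms (fine for small lambda)
  int pois(double lambda) {
    double L = std::exp(-lambda);
    double p = 1.0;
    int k = 0;
    do {
      ++k;
      p *= unif();
    } while (p > L);
    return k - 1;
  }

  // integer in 0..(n-1)
  int pick(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

#endif
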