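#ifndef DRYSPIKE_RNG_H
#define DRYSPIKE_RNG_H

#include <cstdint>
#include <random>

// Deterministic, platform-stable random streams. mt19937_64 raw output is
// fully specified by the C++ standard; all derived draws (bounded integers,
// doubles, Poisson counts) are implemented here so that no unspecified
// library distribution enters the results.

namespace dryspike {

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// One 64-bit seed per (master seed, stream key) pair.
inline uint64_t stream_seed(uint64_t master, uint64_t key) {
  uint64_t x = master ^ (0x9E3779B97F4A7C15ULL * (key + 1));
  (void)splitmix64(x);
  return splitmix64(x);
}

typedef std::mt19937_64 rng_t;

inline rng_t make_stream(uint64_t master, uint64_t key) {
  return rng_t(stream_seed(master, key));
}

// Unbiased draw in [0, n) by rejection.
inline uint64_t draw_bounded(rng_t &g, uint64_t n) {
  if (n <= 1) return 0;
  const uint64_t lim = UINT64_MAX - UINT64_MAX % n;
  uint64_t x;
  do { x = g(); } while (x >= lim);
  return x % n;
}

// Uniform double in [0, 1) with 53 random bits.
inline double draw_unif(rng_t &g) {
  return (g() >> 11) * (1.0 / 9007199254740992.0);
}

// Poisson count, Knuth's product-of-uniforms method (lambda is small in all
// uses here: per-h-step external drive intensities).
inline int draw_poisson(rng_t &g, double lambda) {
  if (lambda <= 0.0) return 0;
  const double L = std::exp(-lambda);
  int k = 0;
  double p = 1.0;
  do {
    ++k;
    p *= draw_unif(g);
  } while (p > L);
  return k - 1;
}

} // namespace dryspike

#endif
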