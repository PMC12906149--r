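#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

// Counter-based per-fiber RNG: each (seed, band, fiber) triple owns an
// independent splitmix64 stream, so the draws for one fiber never depend
// on how many other fibers or bands are simulated.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double unif01(uint64_t &state) {
  return (splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t fiber_stream(uint64_t seed, int band, int fiber) {
  uint64_t s = seed;
  s ^= 0x9E3779B97F4A7C15ULL * (uint64_t)(band + 1);
  s ^= 0xC2B2AE3D27D4EB4FULL * (uint64_t)(fiber + 1);
  // burn a few outputs to decorrelate nearby (band, fiber) seeds
  splitmix64(s);
  splitmix64(s);
  return s;
}

// [[Rcpp::export(name = "spike_kernel")]]
Rcpp::DataFrame spike_kernel(Rcpp::NumericMatrix rates, int n_fibers,
                             double bin_width, double refractory,
                             double depression, double adaptation_tau,
                             double duration, double seed) {
  const int n_bands = rates.nrow();
  const int n_bins = rates.ncol();
  const double decay = std::exp(-bin_width / adaptation_tau);
  double jitter_span = bin_width - refractory;
  if (jitter_span < 0.0) jitter_span = 0.0;
  const uint64_t master = (uint64_t)seed;

  std::vector<int> out_band, out_fiber;
  std::vector<double> out_time;
  out_band.reserve(1024);
  out_fiber.reserve(1024);
  out_time.reserve(1024);

  for (int b = 0; b < n_bands; ++b) {
    for (int f = 0; f < n_fibers; ++f) {
      uint64_t state = fiber_stream(master, b, f);
      double a = 1.0; // adaptation state, 1 = fully recovered
      for (int t = 0; t < n_bins; ++t) {
        const double p = 1.0 - std::exp(-rates(b, t) * a * bin_width);
        if (unif01(state) < p) {
          const double tm = t * bin_width + unif01(state) * jitter_span;
          if (tm < duration) {
            out_band.push_back(b + 1);
            out_fiber.push_back(f + 1);
            out_time.push_back(tm);
          }
          a *= (1.0 - depression);
        }
        a = 1.0 + (a - 1.0) * decay;
      }
    }
  }
  return Rcpp::DataFrame::create(
      Rcpp::Named("band") = out_band,
      Rcpp::Named("fiber") = out_fiber,
      Rcpp::Named("time") = out_time);
}
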