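#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// splitmix64 finaliser; used to fold (master seed, cell index, rep index, ...)
// into a well-mixed 31-bit seed so that parallel and serial sweeps agree.

static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export(name = ".derive_seed_cpp")]]
int derive_seed_cpp(IntegerVector parts) {
  uint64_t x = 0x8000000080003ADULL;
  for (int i = 0; i < parts.size(); ++i)
    x = mix64(x ^ (uint64_t)(uint32_t)parts[i]);
  uint64_t folded = (x ^ (x >> 32)) & 0x7FFFFFFFULL;
  if (folded < 2) folded += 2;  // keep inside set.seed's comfortable range
  return (int)folded;
}
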