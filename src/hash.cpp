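#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// FNV-1a over the name bytes, mixed with the seed and finalized with the
// splitmix64 avalanche so that sequential read names ("frag000001", ...) give
// well-dispersed uniforms. Used by the pair-preserving downsampler: one draw
// per fragment name, so mates always share their fate and kept-sets are
// nested across inclusion probabilities.

static inline uint64_t splitmix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export(name = ".pair_hash01")]]
NumericVector pair_hash01(CharacterVector names, double seed) {
  const uint64_t fnv_offset = 14695981039346656037ULL;
  const uint64_t fnv_prime = 1099511628211ULL;
  uint64_t seed64 = (uint64_t)(int64_t)seed;
  R_xlen_t n = names.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(names, i));
    uint64_t h = fnv_offset ^ splitmix64(seed64);
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= fnv_prime;
    }
    h = splitmix64(h);
    // top 53 bits -> uniform double in [0, 1)
    out[i] = (double)(h >> 11) * (1.0 / 9007199254740992.0);
  }
  return out;
}
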