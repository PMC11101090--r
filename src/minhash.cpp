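#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>

// Bottom-s MinHash sketching of canonical k-mers. k-mers are 2-bit
// encoded (A=0, C=1, G=2, T=3); the canonical form is the minimum of the
// forward and reverse-complement encodings. Hashing is a splitmix64-style
// 64-bit finalizer seeded for reproducibility; values are truncated to 53
// bits so they stay exact in R doubles.

static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".sketch_cpp")]]
Rcpp::NumericVector sketch_cpp(Rcpp::CharacterVector seqs, int k,
                               int sketch_size, double seed) {
  if (k < 1 || k > 31) Rcpp::stop("k must be in 1..31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  const uint64_t seed64 = (uint64_t)seed;
  std::vector<uint64_t> hashes;
  int code[256];
  for (int i = 0; i < 256; ++i) code[i] = -1;
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3;
  code['a'] = 0; code['c'] = 1; code['g'] = 2; code['t'] = 3;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char *q = p; *q; ++q) {
      int c = code[(unsigned char)*q];
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(mix64(canon ^ seed64) >> 11);  // keep 53 bits
      }
    }
  }
  if (hashes.empty()) return Rcpp::NumericVector(0);
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t n = std::min((size_t)sketch_size, hashes.size());
  Rcpp::NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (double)hashes[i];
  return out;
}
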