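#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit hash of a 2-bit-encoded k-mer
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  }
  return -1;
}

// Bottom-s sketch of the canonical k-mer set (min of forward and
// reverse-complement encodings). Hashes are truncated to 53 bits so they
// survive the round trip through R doubles exactly.
// [[Rcpp::export]]
NumericVector cpp_minhash_sketch(std::string seq, int k, int sketch_size,
                                 int seed) {
  const uint64_t mask53 = (1ULL << 53) - 1;
  int n = (int)seq.size();
  std::vector<uint64_t> hashes;
  if (n >= k) {
    uint64_t fwd = 0, rev = 0, kmask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int b = base2bit(seq[i]);
      if (b < 0) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & kmask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(fwd, rev);
        hashes.push_back(mix64(canon ^ (uint64_t)seed) & mask53);
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  int s = std::min((int)hashes.size(), sketch_size);
  NumericVector out(s);
  for (int i = 0; i < s; ++i) out[i] = (double)hashes[i];
  return out;
}

// Mash-style Jaccard estimate from two bottom-s sketches (sorted, distinct):
// take the s smallest of the union and count how many occur in both.
// [[Rcpp::export]]
double cpp_sketch_jaccard(NumericVector a, NumericVector b, int sketch_size) {
  int s = std::min((int)(a.size() + b.size()),
                   std::min(sketch_size, (int)std::max(a.size(), b.size())));
  int i = 0, j = 0, taken = 0, shared = 0;
  while (taken < s && (i < a.size() || j < b.size())) {
    if (j >= b.size() || (i < a.size() && a[i] < b[j])) { ++i; }
    else if (i >= a.size() || b[j] < a[i]) { ++j; }
    else { ++shared; ++i; ++j; }
    ++taken;
  }
  if (taken == 0) return 0.0;
  return (double)shared / (double)taken;
}
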