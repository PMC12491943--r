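#include <Rcpp.h>
#include <set>
#include <cstdint>
using namespace Rcpp;

// splitmix64: deterministic 64-bit mix of the packed canonical k-mer code.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Bottom sketch of the hash values of distinct canonical k-mers. Hashes are
// right-shifted by 11 bits so they are exactly representable as doubles.
// [[Rcpp::export]]
NumericVector cpp_sketch(CharacterVector seqs, int k, int sketch_size) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  if (sketch_size < 1) stop("sketch_size must be >= 1");
  uint64_t mask = (1ULL << (2 * k)) - 1;
  int shift = 2 * (k - 1);
  std::set<uint64_t> bottom;  // holds hash values, smallest sketch_size kept

  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2(s[p]);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        // 2-bit codes preserve lexicographic order, so the numeric min is
        // the lexicographically smaller of k-mer and reverse complement
        uint64_t canon = fwd < rev ? fwd : rev;
        uint64_t h = mix64(canon) >> 11;
        if ((int)bottom.size() < sketch_size) {
          bottom.insert(h);
        } else if (h < *bottom.rbegin()) {
          bottom.insert(h);
          if ((int)bottom.size() > sketch_size)
            bottom.erase(std::prev(bottom.end()));
        }
      }
    }
  }
  NumericVector out(bottom.size());
  int j = 0;
  for (uint64_t h : bottom) out[j++] = (double)h;
  return out;
}
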