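#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// MurmurHash3 x64_128 (Austin Appleby's public-domain algorithm); only the
// first 64-bit half (h1) is used. Fixed seed so signatures are stable
// across sessions and platforms.
static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t murmur3_h1(const char *data, int len, uint32_t seed) {
  const uint8_t *key = reinterpret_cast<const uint8_t *>(data);
  const int nblocks = len / 16;

  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (int i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, key + i * 16, 8);
    std::memcpy(&k2, key + i * 16 + 8, 8);

    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t *tail = key + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= uint64_t(tail[14]) << 48; // fall through
  case 14: k2 ^= uint64_t(tail[13]) << 40; // fall through
  case 13: k2 ^= uint64_t(tail[12]) << 32; // fall through
  case 12: k2 ^= uint64_t(tail[11]) << 24; // fall through
  case 11: k2 ^= uint64_t(tail[10]) << 16; // fall through
  case 10: k2 ^= uint64_t(tail[9]) << 8;   // fall through
  case 9:  k2 ^= uint64_t(tail[8]);
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2; // fall through
  case 8:  k1 ^= uint64_t(tail[7]) << 56; // fall through
  case 7:  k1 ^= uint64_t(tail[6]) << 48; // fall through
  case 6:  k1 ^= uint64_t(tail[5]) << 40; // fall through
  case 5:  k1 ^= uint64_t(tail[4]) << 32; // fall through
  case 4:  k1 ^= uint64_t(tail[3]) << 24; // fall through
  case 3:  k1 ^= uint64_t(tail[2]) << 16; // fall through
  case 2:  k1 ^= uint64_t(tail[1]) << 8;  // fall through
  case 1:  k1 ^= uint64_t(tail[0]);
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= uint64_t(len); h2 ^= uint64_t(len);
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static const uint32_t HASH_SEED = 42u;
// hashes are truncated to 53 bits so every value is exactly representable
// as an R double
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Bottom-n sketch of the canonical k-mer set of `seqs`. K-mers containing
// any non-ACGT character are skipped; each k-mer is canonicalised as the
// lexicographic minimum of itself and its reverse complement before
// hashing. Returns the n smallest distinct hash values, sorted.
// [[Rcpp::export(name = ".sketch_hashes")]]
NumericVector sketch_hashes(CharacterVector seqs, int k, int n_keep) {
  if (k < 1) stop("k must be >= 1");
  if (n_keep < 1) stop("sketch capacity must be >= 1");

  std::unordered_set<uint64_t> seen;
  std::string fwd(k, 'N'), rev(k, 'N');

  for (R_xlen_t s = 0; s < seqs.size(); s++) {
    std::string seq = as<std::string>(seqs[s]);
    const int len = (int)seq.size();
    for (int i = 0; i < len; i++) {
      char c = std::toupper((unsigned char)seq[i]);
      seq[i] = (c == 'A' || c == 'C' || c == 'G' || c == 'T') ? c : 'N';
    }
    if (len < k) continue;
    // prev_bad[i] = position of the most recent non-ACGT char at or before i
    std::vector<int> prev_bad(len);
    int last_bad = -1;
    for (int i = 0; i < len; i++) {
      if (seq[i] == 'N') last_bad = i;
      prev_bad[i] = last_bad;
    }
    for (int i = 0; i + k <= len; i++) {
      if (prev_bad[i + k - 1] >= i) continue; // window contains non-ACGT
      for (int j = 0; j < k; j++) {
        fwd[j] = seq[i + j];
        rev[k - 1 - j] = comp_base(seq[i + j]);
      }
      const std::string &canon = (rev < fwd) ? rev : fwd;
      uint64_t h = murmur3_h1(canon.data(), k, HASH_SEED) & HASH_MASK;
      seen.insert(h);
    }
  }

  std::vector<uint64_t> all(seen.begin(), seen.end());
  size_t keep = std::min<size_t>((size_t)n_keep, all.size());
  if (all.size() > keep)
    std::nth_element(all.begin(), all.begin() + keep, all.end());
  all.resize(keep);
  std::sort(all.begin(), all.end());

  NumericVector out(keep);
  for (size_t i = 0; i < keep; i++) out[i] = (double)all[i];
  return out;
}
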