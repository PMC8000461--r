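#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int8_t base_code(char c) {
  switch (std::toupper((unsigned char)c)) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::vector<int8_t> encode(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); i++) v[i] = base_code(s[i]);
  return v;
}

static std::vector<int8_t> revcomp_codes(const std::vector<int8_t> &v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); i++) {
    int8_t c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? -1 : (int8_t)(3 - c);
  }
  return r;
}

struct Hit {
  double score = -1;   // matches - mismatches of the best ungapped segment
  int matches = 0;
  int cols = 0;        // alignment columns (ungapped: segment length)
  int sstart = -1;     // 0-based subject coordinate of segment start
  int strand = 0;      // +1 forward, -1 reverse
};

// Best maximal-scoring ungapped segment (match +1, mismatch -1, any column
// touching a non-ACGT character counts as mismatch) between fragment codes
// and the subject along one diagonal. Kadane's algorithm; ties within the
// diagonal resolve to the lowest subject coordinate (leftmost segment).
static void scan_diagonal(const std::vector<int8_t> &frag,
                          const std::vector<int8_t> &subj,
                          long diag, int strand, Hit &best) {
  const long flen = (long)frag.size(), slen = (long)subj.size();
  long f0 = std::max(0L, -diag);
  long f1 = std::min(flen, slen - diag);
  if (f1 <= f0) return;

  long cur_start = f0;
  int cur_score = 0, cur_match = 0;
  long best_start = -1, best_end = -1;
  int best_score = 0, best_match = 0;

  for (long f = f0; f < f1; f++) {
    int8_t a = frag[f], b = subj[f + diag];
    bool match = (a >= 0 && a == b);
    int sc = match ? 1 : -1;
    if (cur_score <= 0) { cur_start = f; cur_score = 0; cur_match = 0; }
    cur_score += sc;
    if (match) cur_match++;
    if (cur_score > best_score) {
      best_score = cur_score;
      best_match = cur_match;
      best_start = cur_start;
      best_end = f;
    }
    if (cur_score <= 0) { cur_match = 0; }
  }
  if (best_start < 0) return;

  // cur_match may include matches before cur_start reset; recount exactly
  int m = 0;
  for (long f = best_start; f <= best_end; f++) {
    int8_t a = frag[f], b = subj[f + diag];
    if (a >= 0 && a == b) m++;
  }
  int cols = (int)(best_end - best_start + 1);
  int sstart = (int)(best_start + diag);
  if (best_score > best.score ||
      (best_score == best.score && sstart < best.sstart)) {
    best.score = best_score;
    best.matches = m;
    best.cols = cols;
    best.sstart = sstart;
    best.strand = strand;
  }
}

// Seeded ungapped local alignment of each query fragment against the
// subject genome (all contigs concatenated by the caller with 'N' joints so
// segments never span contigs). Exact-match seeding on `word`-length
// words, per-diagonal Kadane extension, both strands of the fragment.
// Returns one row per fragment: identity %, coverage % (columns on the
// fragment / fragment length), score, subject start (1-based), strand.
// Fragments with no seed hit get identity/coverage -1.
// [[Rcpp::export(name = ".fragment_hits")]]
NumericMatrix fragment_hits(CharacterVector fragments, CharacterVector subject,
                            int word) {
  if (word < 4 || word > 15) stop("word size must be in [4, 15]");
  std::string subj_s = as<std::string>(subject[0]);
  std::vector<int8_t> subj = encode(subj_s);
  const long slen = (long)subj.size();

  // index every valid word position of the subject
  std::unordered_map<uint32_t, std::vector<int32_t> > index;
  if (slen >= word) {
    uint32_t code = 0, mask = (1u << (2 * word)) - 1;
    int run = 0; // length of current valid run
    for (long i = 0; i < slen; i++) {
      int8_t c = subj[i];
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      run++;
      if (run >= word) index[code].push_back((int32_t)(i - word + 1));
    }
  }

  const R_xlen_t nfrag = fragments.size();
  NumericMatrix out(nfrag, 5);
  colnames(out) = CharacterVector::create("identity", "coverage", "score",
                                          "sstart", "strand");

  for (R_xlen_t fi = 0; fi < nfrag; fi++) {
    std::string frag_s = as<std::string>(fragments[fi]);
    std::vector<int8_t> fwd = encode(frag_s);
    const long flen = (long)fwd.size();
    Hit best;

    for (int strand = 0; strand < 2; strand++) {
      const std::vector<int8_t> frag =
        (strand == 0) ? fwd : revcomp_codes(fwd);
      if (flen < word) continue;
      std::unordered_set<long> diags;
      uint32_t code = 0, mask = (1u << (2 * word)) - 1;
      int run = 0;
      for (long i = 0; i < flen; i++) {
        int8_t c = frag[i];
        if (c < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | (uint32_t)c) & mask;
        run++;
        if (run < word) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        long fpos = i - word + 1;
        for (int32_t spos : it->second) diags.insert((long)spos - fpos);
      }
      std::vector<long> dsort(diags.begin(), diags.end());
      std::sort(dsort.begin(), dsort.end());
      for (long d : dsort)
        scan_diagonal(frag, subj, d, strand == 0 ? 1 : -1, best);
    }

    if (best.sstart < 0) {
      out(fi, 0) = -1; out(fi, 1) = -1; out(fi, 2) = -1;
      out(fi, 3) = NA_REAL; out(fi, 4) = NA_REAL;
    } else {
      out(fi, 0) = 100.0 * best.matches / best.cols;
      out(fi, 1) = 100.0 * best.cols / (double)flen;
      out(fi, 2) = best.score;
      out(fi, 3) = best.sstart + 1;
      out(fi, 4) = best.strand;
    }
  }
  return out;
}
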