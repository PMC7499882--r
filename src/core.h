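#ifndef CCDBG_CORE_H
#define CCDBG_CORE_H

#include <cstdint>
#include <string>
#include <vector>
#include <deque>
#include <stdexcept>

// 2-bit DNA codes, MSB-first so numeric order on codes == lexicographic
// order on the strings they encode (A=0 < C=1 < G=2 < T=3).

inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

inline char code_base(int b) { return "ACGT"[b & 3]; }

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

inline bool valid_dna(const std::string& s) {
  for (char c : s) if (base_code(c) < 0) return false;
  return true;
}

inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

inline std::string canonical_str(const std::string& s) {
  std::string r = revcomp_str(s);
  return (s <= r) ? s : r;
}

inline uint64_t mask_for(int len) {
  return (len >= 32) ? ~0ULL : ((1ULL << (2 * len)) - 1ULL);
}

inline uint64_t encode_dna(const std::string& s, size_t pos, int len) {
  uint64_t v = 0;
  for (int i = 0; i < len; ++i) {
    int b = base_code(s[pos + i]);
    if (b < 0) throw std::runtime_error("non-ACGT symbol in DNA string");
    v = (v << 2) | (uint64_t)b;
  }
  return v;
}

inline std::string decode_dna(uint64_t v, int len) {
  std::string s((size_t)len, 'A');
  for (int i = len - 1; i >= 0; --i) { s[(size_t)i] = code_base((int)(v & 3ULL)); v >>= 2; }
  return s;
}

inline uint64_t revcomp_code(uint64_t v, int len) {
  uint64_t r = 0;
  for (int i = 0; i < len; ++i) { r = (r << 2) | (3ULL - (v & 3ULL)); v >>= 2; }
  return r;
}

inline uint64_t canon_code(uint64_t v, int len) {
  uint64_t r = revcomp_code(v, len);
  return v < r ? v : r;
}

// seeded hash of the canonical g-mer: a g-mer and its reverse complement
// hash equal, giving a strand-symmetric random minimizer order
inline uint64_t gmer_hash_code(uint64_t canon_gcode, uint64_t seed) {
  return splitmix64(canon_gcode ^ seed);
}

// one minimizer occurrence: canonical g-mer code, its hash, and the 0-based
// start position of the occurrence within the host sequence
struct MiniOcc {
  uint64_t gcode;
  uint64_t hash;
  int pos;
};

// rolling 2-bit encoder for g-mers (forward and reverse-complement codes
// updated in O(1) per pushed base)
struct GmerRoller {
  int g; uint64_t seed, mask;
  uint64_t fwd = 0, rc = 0;
  int filled = 0;
  GmerRoller(int g_, uint64_t seed_) : g(g_), seed(seed_), mask(mask_for(g_)) {}
  void push(char c) {
    uint64_t b = (uint64_t)base_code(c);
    fwd = ((fwd << 2) | b) & mask;
    rc = (rc >> 2) | ((3ULL - b) << (2 * (g - 1)));
    if (filled < g) ++filled;
  }
  uint64_t canon() const { return fwd < rc ? fwd : rc; }
  uint64_t hash() const { return gmer_hash_code(canon(), seed); }
};

// interior g-mer occurrences of the k-mer starting at `pos` in `s`
// (window offsets 1 .. k-g-1 within the k-mer), in position order
inline std::vector<MiniOcc> interior_gmers(const std::string& s, size_t pos,
                                           int k, int g, uint64_t seed) {
  std::vector<MiniOcc> out;
  if (g > k - 2) throw std::runtime_error("g must satisfy g <= k - 2");
  GmerRoller r(g, seed);
  for (int i = 1; i < 1 + g - 1; ++i) r.push(s[pos + i]);
  for (int off = 1; off <= k - g - 1; ++off) {
    r.push(s[pos + off + g - 1]);
    out.push_back({r.canon(), r.hash(), off});
  }
  return out;
}

// minimizer of one k-mer: smallest interior hash, leftmost on ties
inline MiniOcc minimizer_of_kmer(const std::string& s, size_t pos,
                                 int k, int g, uint64_t seed) {
  std::vector<MiniOcc> cand = interior_gmers(s, pos, k, g, seed);
  MiniOcc best = cand[0];
  for (const auto& m : cand) if (m.hash < best.hash) best = m;
  return best;
}

inline MiniOcc minimizer_of_code(uint64_t fwd_code, int k, int g, uint64_t seed) {
  std::string s = decode_dna(fwd_code, k);
  return minimizer_of_kmer(s, 0, k, g, seed);
}

// allocation-free minimizer hash of a packed k-mer (the only part the
// filter needs); equals minimizer_of_code(...).hash
inline uint64_t min_interior_hash(uint64_t fwd_code, int k, int g, uint64_t seed) {
  uint64_t best = ~0ULL;
  uint64_t gmask = mask_for(g);
  for (int off = 1; off <= k - g - 1; ++off) {
    uint64_t gm = (fwd_code >> (2 * (k - off - g))) & gmask;
    uint64_t h = gmer_hash_code(canon_code(gm, g), seed);
    if (h < best) best = h;
  }
  return best;
}

// minimizers for every k-mer of an ACGT run, ascending-minima sliding
// window: amortised O(1) per k-mer. pos in each MiniOcc is absolute within
// the run; equal-hash ties resolve to the leftmost position.
inline std::vector<MiniOcc> run_minimizers(const std::string& run,
                                           int k, int g, uint64_t seed) {
  int n = (int)run.size();
  std::vector<MiniOcc> out;
  if (n < k) return out;
  out.reserve((size_t)(n - k + 1));
  std::deque<MiniOcc> dq;
  GmerRoller r(g, seed);
  for (int i = 0; i < g - 1; ++i) r.push(run[(size_t)i]);
  int next_g = 0; // next g-mer start position to admit
  for (int i = 0; i + k <= n; ++i) {
    int lo = i + 1, hi = i + k - g - 1;
    while (next_g <= hi) {
      r.push(run[(size_t)(next_g + g - 1)]);
      if (next_g >= lo) {
        MiniOcc m{r.canon(), r.hash(), next_g};
        while (!dq.empty() && dq.back().hash > m.hash) dq.pop_back();
        dq.push_back(m);
      }
      ++next_g;
    }
    while (!dq.empty() && dq.front().pos < lo) dq.pop_front();
    out.push_back(dq.front());
  }
  return out;
}

// maximal ACGT runs of a sequence as (start, length) pairs
inline std::vector<std::pair<size_t, size_t> > acgt_runs(const std::string& s) {
  std::vector<std::pair<size_t, size_t> > runs;
  size_t i = 0, n = s.size();
  while (i < n) {
    while (i < n && base_code(s[i]) < 0) ++i;
    size_t j = i;
    while (j < n && base_code(s[j]) >= 0) ++j;
    if (j > i) runs.push_back(std::make_pair(i, j - i));
    i = j;
  }
  return runs;
}

#endif
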