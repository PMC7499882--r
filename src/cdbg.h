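#ifndef CCDBG_CDBG_H
#define CCDBG_CDBG_H

#include "core.h"
#include "bbf.h"
#include <unordered_map>
#include <unordered_set>
#include <map>
#include <set>
#include <algorithm>

// ---------------------------------------------------------------------------
// color containers: per-unitig eta x |C| presence matrices in three tiers
//   0 "word"   : one 64-bit word; either a single (i,j) pair or a full bit
//                matrix when eta*|C| <= 62 (2 bits of metadata)
//   1 "medium" : pair set bounded by 65488 pairs and an 8 KB serialized-size
//                budget (min of bit-matrix and 4-byte-per-pair encodings)
//   2 "large"  : unbounded pair set
// pairs are packed (row i << 32) | color j; membership is tier-transparent
// ---------------------------------------------------------------------------
struct ColorContainer {
  uint8_t tier = 0;   // 0 word, 1 medium, 2 large
  uint8_t wmode = 0;  // word tier: 0 empty, 1 single pair, 2 bit matrix
  uint64_t word = 0;
  std::unordered_set<uint64_t> pairs;

  static uint64_t pack(uint32_t i, uint32_t j) { return ((uint64_t)i << 32) | j; }

  static const uint32_t MEDIUM_MAX_PAIRS = 65488;
  static const uint32_t MEDIUM_MAX_BYTES = 8192;

  static bool medium_fits(uint64_t eta, uint64_t nc, uint64_t npairs) {
    if (npairs > MEDIUM_MAX_PAIRS) return false;
    uint64_t bit_bytes = (eta * nc + 7) / 8;
    uint64_t list_bytes = 4 * npairs;
    return bit_bytes <= MEDIUM_MAX_BYTES || list_bytes <= MEDIUM_MAX_BYTES;
  }

  void to_pairs_tier(uint8_t t, uint64_t eta, uint64_t nc) {
    if (tier == 0) {
      std::unordered_set<uint64_t> p;
      if (wmode == 1) p.insert(word);
      else if (wmode == 2) {
        for (uint64_t b = 0; b < eta * nc; ++b)
          if ((word >> b) & 1ULL) p.insert(pack((uint32_t)(b / nc), (uint32_t)(b % nc)));
      }
      pairs.swap(p);
    }
    tier = t;
    wmode = 0; word = 0;
  }

  void add(uint32_t i, uint32_t j, uint64_t eta, uint64_t nc) {
    uint64_t pr = pack(i, j);
    if (tier == 0) {
      if (wmode == 0) { wmode = 1; word = pr; return; }
      if (wmode == 1) {
        if (word == pr) return;
        if (eta * nc <= 62) {
          uint64_t old = word;
          wmode = 2; word = 0;
          word |= 1ULL << ((old >> 32) * nc + (old & 0xFFFFFFFFULL));
          word |= 1ULL << ((uint64_t)i * nc + j);
          return;
        }
        to_pairs_tier(1, eta, nc);
        pairs.insert(pr);
        return;
      }
      // bit matrix
      word |= 1ULL << ((uint64_t)i * nc + j);
      return;
    }
    pairs.insert(pr);
    if (tier == 1 && !medium_fits(eta, nc, pairs.size())) tier = 2;
  }

  bool has(uint32_t i, uint32_t j, uint64_t nc) const {
    uint64_t pr = pack(i, j);
    if (tier == 0) {
      if (wmode == 0) return false;
      if (wmode == 1) return word == pr;
      return (word >> ((uint64_t)i * nc + j)) & 1ULL;
    }
    return pairs.count(pr) > 0;
  }

  std::vector<std::pair<uint32_t, uint32_t> > all_pairs(uint64_t eta, uint64_t nc) const {
    std::vector<std::pair<uint32_t, uint32_t> > out;
    if (tier == 0) {
      if (wmode == 1) out.push_back(std::make_pair((uint32_t)(word >> 32), (uint32_t)(word & 0xFFFFFFFFULL)));
      else if (wmode == 2) {
        for (uint64_t b = 0; b < eta * nc; ++b)
          if ((word >> b) & 1ULL) out.push_back(std::make_pair((uint32_t)(b / nc), (uint32_t)(b % nc)));
      }
      return out;
    }
    out.reserve(pairs.size());
    for (uint64_t p : pairs) out.push_back(std::make_pair((uint32_t)(p >> 32), (uint32_t)(p & 0xFFFFFFFFULL)));
    return out;
  }

  void clear() { tier = 0; wmode = 0; word = 0; pairs.clear(); }

  // bit-matrix layout depends on |C|; re-encode when a color is added
  void rebase_ncolors(uint64_t eta, uint64_t old_nc, uint64_t new_nc) {
    if (tier == 0 && wmode == 2) {
      std::vector<std::pair<uint32_t, uint32_t> > p = all_pairs(eta, old_nc);
      wmode = 0; word = 0;
      if (eta * new_nc <= 62) {
        wmode = 2;
        for (size_t q = 0; q < p.size(); ++q)
          word |= 1ULL << ((uint64_t)p[q].first * new_nc + p[q].second);
      } else {
        tier = 1;
        for (size_t q = 0; q < p.size(); ++q) pairs.insert(pack(p[q].first, p[q].second));
        if (!medium_fits(eta, new_nc, pairs.size())) tier = 2;
      }
    } else if (tier == 1 && !medium_fits(eta, old_nc, pairs.size())) {
      tier = 2;
    }
  }
};

// slot assignment: array O of containers, seeds H tried in order on the
// unitig's head k-mer, hash table K as fallback. The resolved container
// index is stored on the unitig record, so graph edits elsewhere never
// move or re-resolve a container.
struct ColorStore {
  bool active = false;
  std::vector<std::string> color_names;
  std::vector<ColorContainer> O;
  std::vector<char> claimed;
  size_t n_claimed = 0;
  std::vector<uint64_t> H;
  std::unordered_map<uint64_t, int> K; // head k-mer code -> slot
  uint64_t n_fallback = 0;

  void init(uint64_t seed, int n_seeds = 16) {
    active = true;
    H.clear();
    for (int i = 0; i < n_seeds; ++i) H.push_back(splitmix64(seed ^ (0x1000ULL + (uint64_t)i)));
    if (O.empty()) { O.resize(16); claimed.assign(16, 0); }
  }
};

struct Unitig {
  std::string seq;
  bool live = false;
  std::vector<uint8_t> counters;              // saturating at 2; build phase
  int color_slot = -1;
  std::vector<std::pair<uint64_t, int> > mins; // (gcode, pos) entries in M
};

struct MinList {
  std::vector<std::pair<int, int> > tuples; // (unitig id, g-mer pos in unitig)
  bool recurrent = false;                   // sticky once size has reached t
};

struct LookupHit {
  bool found = false;
  int id = -1;
  int offset = -1;    // 0-based k-mer start in the stored unitig sequence
  bool forward = true;
};

struct Cdbg {
  int k, g, t;
  uint64_t seed;
  std::vector<Unitig> U;
  std::vector<int> free_ids;
  size_t n_live = 0;
  std::unordered_map<uint64_t, MinList> M;
  std::unordered_map<uint64_t, uint64_t> ghosts; // canon k-mer -> anchor
  ColorStore colors;
  // stats
  uint64_t n_ghost_repairs = 0, n_fp_deleted = 0, n_splits = 0, n_joins = 0;

  Cdbg(int k_, int g_, int t_, uint64_t seed_) : k(k_), g(g_), t(t_), seed(seed_) {}

  int insert_unitig(const std::string& seq);
  int insert_unitig_full(const std::string& seq, const std::vector<uint8_t>* ctr,
                         const std::vector<std::pair<uint32_t, uint32_t> >* color_pairs);
  void remove_unitig(int id);
  LookupHit lookup(const std::string& kmer) const;
  LookupHit lookup_code(uint64_t canon, uint64_t fwd) const;

  // minimizer selection for insertion with the recurrent fallback
  MiniOcc select_insert_minimizer(const std::string& s, size_t pos,
                                  bool* fallback, bool* overflow) const;

  size_t n_kmers() const {
    size_t n = 0;
    for (const auto& u : U) if (u.live) n += u.seq.size() - (size_t)k + 1;
    return n;
  }

  std::string oriented(int id, bool forward) const {
    return forward ? U[(size_t)id].seq : revcomp_str(U[(size_t)id].seq);
  }
};

// orientation convention: a unitig is stored as min(seq, revcomp(seq));
// returns true if the input was kept as-is
inline bool normalize_unitig(std::string& s) {
  std::string r = revcomp_str(s);
  if (r < s) { s.swap(r); return false; }
  return true;
}

// construct.cpp
struct ExtractInstr {
  std::vector<int> step_probes, step_hits;
};
std::string extract_unitig_core(Membership& mb, uint64_t x_fwd, int k, int g,
                                uint64_t seed,
                                std::unordered_map<uint64_t, uint64_t>* ghosts,
                                const Cdbg* D, ExtractInstr* instr);
void build_pass(Cdbg& D, Membership& mb, const std::vector<std::string>& seqs);
void eliminate_fp(Cdbg& D, int threshold);
void join_sweep(Cdbg& D);
void split_at_branches(Cdbg& D);
void cdbg_update_kmers(Cdbg& D, const std::vector<uint64_t>& new_kmers);

// colors.cpp
int assign_slot(Cdbg& D, int id);
void color_add(Cdbg& D, int id, uint32_t row, uint32_t col);
void release_slot(Cdbg& D, int id);
void register_color(Cdbg& D, const std::string& name);
std::vector<std::pair<uint32_t, uint32_t> > unitig_color_pairs(const Cdbg& D, int id);

#endif
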