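#ifndef CCDBG_BBF_H
#define CCDBG_BBF_H

#include "core.h"
#include <unordered_set>
#include <cmath>

// Blocked Bloom filter: an array of 512-bit blocks (one cache line).
// The block pair for an element comes from two hashes of its minimizer
// hash (2-choice), the f probe bits from double hashing of two hashes of
// the canonical k-mer code. Single-writer: no concurrent mutation.
struct BBF {
  static const int BLOCK_BITS = 512;
  static const int BLOCK_WORDS = 8;
  int f;
  uint64_t nb_blocks;
  uint64_t s_b1, s_b2, s_h1, s_h2;
  bool two_choice;
  std::vector<uint64_t> bits;
  std::vector<uint32_t> occ; // exact per-block set-bit counts

  BBF(double n_expected, double bits_per_elem, uint64_t seed, bool two_choice_ = true)
      : two_choice(two_choice_) {
    if (n_expected < 1) n_expected = 1;
    double m = n_expected * bits_per_elem;
    nb_blocks = (uint64_t)std::ceil(m / BLOCK_BITS);
    if (nb_blocks < 1) nb_blocks = 1;
    f = (int)std::lround(bits_per_elem * std::log(2.0));
    if (f < 1) f = 1;
    if (f > 48) f = 48; // probe buffer bound; far past any useful sizing
    s_b1 = splitmix64(seed ^ 0x42ULL);
    s_b2 = splitmix64(seed ^ 0x43ULL);
    s_h1 = splitmix64(seed ^ 0x44ULL);
    s_h2 = splitmix64(seed ^ 0x45ULL);
    bits.assign(nb_blocks * BLOCK_WORDS, 0ULL);
    occ.assign(nb_blocks, 0);
  }

  uint64_t cand1(uint64_t minhash) const { return splitmix64(minhash ^ s_b1) % nb_blocks; }
  uint64_t cand2(uint64_t minhash) const {
    return two_choice ? splitmix64(minhash ^ s_b2) % nb_blocks : cand1(minhash);
  }

  // enhanced (triangular) double hashing: position_i = h1 + i*h2 + C(i+1,3).
  // The triangular term avoids the aligned-progression correlations of
  // plain double hashing inside a small block; the sequence is walked past
  // f when needed so the f probe positions are distinct.
  void probe_positions(uint64_t code, uint64_t* pos) const {
    uint64_t h1 = splitmix64(code ^ s_h1);
    uint64_t h2 = splitmix64(code ^ s_h2) | 1ULL;
    int got = 0;
    for (uint64_t i = 0; got < f && i < 4 * (uint64_t)f + 16; ++i) {
      uint64_t idx = (h1 + i * h2 + (i * (i * i - 1)) / 6) % BLOCK_BITS;
      bool dup = false;
      for (int j = 0; j < got; ++j) if (pos[j] == idx) { dup = true; break; }
      if (!dup) pos[got++] = idx;
    }
    while (got < f) pos[got++] = pos[0]; // unreachable in practice
  }

  bool contains_block(uint64_t blk, const uint64_t* pos) const {
    const uint64_t* b = &bits[blk * BLOCK_WORDS];
    for (int i = 0; i < f; ++i) {
      uint64_t idx = pos[i];
      if (!((b[idx >> 6] >> (idx & 63)) & 1ULL)) return false;
    }
    return true;
  }

  bool may_contain(uint64_t code, uint64_t minhash) const {
    uint64_t pos[64];
    probe_positions(code, pos);
    uint64_t b1 = cand1(minhash);
    if (contains_block(b1, pos)) return true;
    uint64_t b2 = cand2(minhash);
    return b2 != b1 && contains_block(b2, pos);
  }

  // returns the block the element lives in after the call; if one of the
  // candidate blocks already holds the element no write occurs
  uint64_t insert(uint64_t code, uint64_t minhash) {
    uint64_t pos[64];
    probe_positions(code, pos);
    uint64_t b1 = cand1(minhash), b2 = cand2(minhash);
    if (contains_block(b1, pos)) return b1;
    if (b2 != b1 && contains_block(b2, pos)) return b2;
    uint64_t blk = (occ[b1] <= occ[b2]) ? b1 : b2;
    uint64_t* b = &bits[blk * BLOCK_WORDS];
    uint32_t added = 0;
    for (int i = 0; i < f; ++i) {
      uint64_t idx = pos[i];
      uint64_t m = 1ULL << (idx & 63);
      if (!(b[idx >> 6] & m)) { b[idx >> 6] |= m; ++added; }
    }
    occ[blk] += added;
    return blk;
  }

  uint64_t total_set_bits() const {
    uint64_t s = 0;
    for (uint32_t o : occ) s += o;
    return s;
  }
};

// membership abstraction used by unitig extraction / graph construction:
// either a BBF (approximate) or an exact k-mer set (oracle-style filter).
// Query/hit counters support probe-accounting instrumentation.
struct Membership {
  uint64_t n_queries = 0, n_hits = 0;
  virtual bool has(uint64_t canon_kmer, uint64_t minhash) const = 0;
  bool query(uint64_t canon_kmer, uint64_t minhash) {
    ++n_queries;
    bool r = has(canon_kmer, minhash);
    if (r) ++n_hits;
    return r;
  }
  virtual ~Membership() {}
};

struct BbfMembership : Membership {
  const BBF* b;
  explicit BbfMembership(const BBF* b_) : b(b_) {}
  bool has(uint64_t code, uint64_t minhash) const { return b->may_contain(code, minhash); }
};

struct ExactMembership : Membership {
  std::unordered_set<uint64_t> set;
  bool has(uint64_t code, uint64_t) const { return set.count(code) > 0; }
};

#endif
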