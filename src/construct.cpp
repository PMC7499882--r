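#include <Rcpp.h>
#include "cdbg.h"
#include <random>
#include <memory>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// neighbor probing
// ---------------------------------------------------------------------------

// forward-oriented codes of the present neighbors of `cur` in one direction
static std::vector<uint64_t> present_neighbors(Membership& mb, uint64_t cur,
                                               bool forward, int k, int g,
                                               uint64_t seed) {
  std::vector<uint64_t> out;
  uint64_t maskk = mask_for(k);
  for (uint64_t a = 0; a < 4; ++a) {
    uint64_t nb = forward ? (((cur << 2) | a) & maskk)
                          : ((a << (2 * (k - 1))) | (cur >> 2));
    uint64_t c = canon_code(nb, k);
    uint64_t mh = min_interior_hash(nb, k, g, seed);
    if (mb.query(c, mh)) out.push_back(nb);
  }
  return out;
}

// ghost test: candidate `s` (forward code) reached from anchor; a ghost has
// no neighbor in the filter other than the anchor. Known ghosts stay
// ghosts; a k-mer already living in a unitig of the graph is real and is
// never ghosted (it may legitimately be a single-k-mer dead-end branch).
static bool is_ghost(Membership& mb, uint64_t s, uint64_t anchor_canon,
                     int k, int g, uint64_t seed,
                     std::unordered_map<uint64_t, uint64_t>* ghosts,
                     const Cdbg* D,
                     const std::unordered_set<uint64_t>& visited) {
  uint64_t c = canon_code(s, k);
  if (visited.count(c)) return false; // part of the very unitig being built
  auto it = ghosts->find(c);
  if (it != ghosts->end()) return true;
  if (D && D->lookup(decode_dna(c, k)).found) return false;
  uint64_t maskk = mask_for(k);
  for (int dir = 0; dir < 2; ++dir) {
    for (uint64_t a = 0; a < 4; ++a) {
      uint64_t nb = dir == 0 ? (((s << 2) | a) & maskk)
                             : ((a << (2 * (k - 1))) | (s >> 2));
      uint64_t nc = canon_code(nb, k);
      if (nc == anchor_canon) continue;
      uint64_t mh = min_interior_hash(nb, k, g, seed);
      if (mb.query(nc, mh)) return false;
    }
  }
  (*ghosts)[c] = anchor_canon;
  return true;
}

// ---------------------------------------------------------------------------
// unitig extraction (forward + backward via the reverse complement)
// ---------------------------------------------------------------------------

static void extend_forward(Membership& mb, uint64_t start, int k, int g,
                           uint64_t seed,
                           std::unordered_map<uint64_t, uint64_t>* ghosts,
                           const Cdbg* D,
                           std::unordered_set<uint64_t>& visited,
                           std::string& appended, ExtractInstr* instr) {
  uint64_t cur = start;
  for (;;) {
    uint64_t q0 = mb.n_queries, h0 = mb.n_hits;
    std::vector<uint64_t> succs = present_neighbors(mb, cur, true, k, g, seed);
    uint64_t cur_canon = canon_code(cur, k);
    if (ghosts && succs.size() != 1) {
      std::vector<uint64_t> keep;
      for (uint64_t s : succs)
        if (!is_ghost(mb, s, cur_canon, k, g, seed, ghosts, D, visited)) keep.push_back(s);
      succs.swap(keep);
    }
    if (succs.size() != 1) break;
    uint64_t s = succs[0];
    std::vector<uint64_t> preds = present_neighbors(mb, s, false, k, g, seed);
    if (ghosts && preds.size() != 1) {
      uint64_t s_canon = canon_code(s, k);
      std::vector<uint64_t> keep;
      for (uint64_t p : preds)
        if (!is_ghost(mb, p, s_canon, k, g, seed, ghosts, D, visited)) keep.push_back(p);
      preds.swap(keep);
    }
    if (preds.size() != 1) break;
    if (canon_code(preds[0], k) != cur_canon) break;
    uint64_t s_canon = canon_code(s, k);
    if (visited.count(s_canon)) break; // cycle guard
    visited.insert(s_canon);
    appended.push_back(code_base((int)(s & 3ULL)));
    cur = s;
    if (instr) {
      instr->step_probes.push_back((int)(mb.n_queries - q0));
      instr->step_hits.push_back((int)(mb.n_hits - h0));
    }
  }
}

std::string extract_unitig_core(Membership& mb, uint64_t x_fwd, int k, int g,
                                uint64_t seed,
                                std::unordered_map<uint64_t, uint64_t>* ghosts,
                                const Cdbg* D, ExtractInstr* instr) {
  std::unordered_set<uint64_t> visited;
  visited.insert(canon_code(x_fwd, k));
  std::string right, left;
  extend_forward(mb, x_fwd, k, g, seed, ghosts, D, visited, right, instr);
  extend_forward(mb, revcomp_code(x_fwd, k), k, g, seed, ghosts, D, visited, left, instr);
  return revcomp_str(left) + decode_dna(x_fwd, k) + right;
}

// ---------------------------------------------------------------------------
// orientation-aware insertion with counters and color rows
// ---------------------------------------------------------------------------

static int insert_oriented(Cdbg& D, std::string seq, std::vector<uint8_t> ctr,
                           std::vector<std::pair<uint32_t, uint32_t> > cps) {
  bool kept = normalize_unitig(seq);
  size_t eta = seq.size() - (size_t)D.k + 1;
  if (!kept) {
    std::reverse(ctr.begin(), ctr.end());
    for (auto& cp : cps) cp.first = (uint32_t)(eta - 1) - cp.first;
  }
  return D.insert_unitig_full(seq, &ctr, cps.empty() ? nullptr : &cps);
}

// ---------------------------------------------------------------------------
// ghost repair: remove the unitigs adjacent to the un-ghosted k-mer and
// re-extract through it, transferring counters (and colors) by k-mer
// ---------------------------------------------------------------------------

static void repair_ghost(Cdbg& D, Membership& mb, uint64_t c) {
  D.ghosts.erase(c);
  ++D.n_ghost_repairs;
  int k = D.k;
  uint64_t maskk = mask_for(k);
  std::set<int> ids;
  for (int dir = 0; dir < 2; ++dir) {
    for (uint64_t a = 0; a < 4; ++a) {
      uint64_t nb = dir == 0 ? (((c << 2) | a) & maskk)
                             : ((a << (2 * (k - 1))) | (c >> 2));
      LookupHit h = D.lookup(decode_dna(nb, k));
      if (h.found) ids.insert(h.id);
    }
  }
  std::unordered_map<uint64_t, uint8_t> saved_ctr;
  std::unordered_map<uint64_t, std::vector<uint32_t> > saved_col;
  std::vector<uint64_t> saved_codes;
  for (int id : ids) {
    const Unitig& u = D.U[(size_t)id];
    size_t eta = u.seq.size() - (size_t)k + 1;
    std::vector<std::pair<uint32_t, uint32_t> > cps = unitig_color_pairs(D, id);
    std::vector<std::vector<uint32_t> > rows(eta);
    for (auto& cp : cps) rows[cp.first].push_back(cp.second);
    for (size_t i = 0; i < eta; ++i) {
      uint64_t code = canon_code(encode_dna(u.seq, i, k), k);
      saved_ctr[code] = u.counters[i];
      if (!rows[i].empty()) saved_col[code] = rows[i];
      saved_codes.push_back(code);
    }
  }
  for (int id : ids) D.remove_unitig(id);
  std::vector<uint64_t> starts;
  starts.push_back(c);
  starts.insert(starts.end(), saved_codes.begin(), saved_codes.end());
  for (uint64_t st : starts) {
    if (D.lookup(decode_dna(st, k)).found) continue;
    std::string useq = extract_unitig_core(mb, st, k, D.g, D.seed, &D.ghosts, &D, nullptr);
    normalize_unitig(useq);
    size_t eta = useq.size() - (size_t)k + 1;
    std::vector<uint8_t> ctr(eta, 0);
    std::vector<std::pair<uint32_t, uint32_t> > cps;
    for (size_t i = 0; i < eta; ++i) {
      uint64_t code = canon_code(encode_dna(useq, i, k), k);
      auto it = saved_ctr.find(code);
      if (it != saved_ctr.end()) ctr[i] = it->second;
      auto ic = saved_col.find(code);
      if (ic != saved_col.end())
        for (uint32_t j : ic->second) cps.push_back(std::make_pair((uint32_t)i, j));
    }
    D.insert_unitig_full(useq, &ctr, cps.empty() ? nullptr : &cps);
  }
}

// ---------------------------------------------------------------------------
// second pass over the reads: extract unitigs, count k-mer occurrences
// ---------------------------------------------------------------------------

void build_pass(Cdbg& D, Membership& mb, const std::vector<std::string>& seqs) {
  int k = D.k, g = D.g;
  uint64_t sd = D.seed;
  for (const std::string& s : seqs) {
    for (const auto& run : acgt_runs(s)) {
      if (run.second < (size_t)k) continue;
      std::string sub = s.substr(run.first, run.second);
      std::vector<MiniOcc> mins = run_minimizers(sub, k, g, sd);
      for (size_t j = 0; j < mins.size(); ++j) {
        uint64_t fwd = encode_dna(sub, j, k);
        uint64_t c = canon_code(fwd, k);
        if (!mb.query(c, mins[j].hash)) continue; // filtered out
        if (D.ghosts.count(c)) repair_ghost(D, mb, c);
        std::string km = sub.substr(j, (size_t)k);
        LookupHit h = D.lookup(km);
        if (!h.found) {
          std::string useq = extract_unitig_core(mb, fwd, k, g, sd, &D.ghosts, &D, nullptr);
          normalize_unitig(useq);
          D.insert_unitig(useq);
          h = D.lookup(km);
          if (!h.found) continue;
        }
        std::vector<uint8_t>& ctr = D.U[(size_t)h.id].counters;
        if (ctr[(size_t)h.offset] < 2) ++ctr[(size_t)h.offset];
      }
    }
  }
}

// ---------------------------------------------------------------------------
// split / join machinery
// ---------------------------------------------------------------------------

static int graph_succ_count(const Cdbg& D, const std::string& kmer,
                            LookupHit* only, std::string* only_str) {
  int k = D.k, found = 0;
  std::string cand = kmer.substr(1) + "A";
  for (int a = 0; a < 4; ++a) {
    cand[(size_t)k - 1] = code_base(a);
    LookupHit h = D.lookup(cand);
    if (h.found) {
      ++found;
      if (only) *only = h;
      if (only_str) *only_str = cand;
    }
  }
  return found;
}

static int graph_pred_count(const Cdbg& D, const std::string& kmer) {
  int found = 0;
  std::string cand = "A" + kmer.substr(0, kmer.size() - 1);
  for (int a = 0; a < 4; ++a) {
    cand[0] = code_base(a);
    if (D.lookup(cand).found) ++found;
  }
  return found;
}

// split one unitig into kept index ranges [a,b] (k-mer indices, inclusive)
static void split_unitig(Cdbg& D, int id,
                         const std::vector<std::pair<int, int> >& keep) {
  const Unitig u = D.U[(size_t)id]; // copy
  std::vector<std::pair<uint32_t, uint32_t> > cps = unitig_color_pairs(D, id);
  int k = D.k;
  D.remove_unitig(id);
  for (const auto& range : keep) {
    int a = range.first, b = range.second;
    std::string piece = u.seq.substr((size_t)a, (size_t)(b - a + k));
    std::vector<uint8_t> ctr(u.counters.begin() + a, u.counters.begin() + b + 1);
    std::vector<std::pair<uint32_t, uint32_t> > pc;
    for (const auto& cp : cps)
      if ((int)cp.first >= a && (int)cp.first <= b)
        pc.push_back(std::make_pair(cp.first - (uint32_t)a, cp.second));
    insert_oriented(D, piece, ctr, pc);
  }
  if (keep.size() > 1) D.n_splits += keep.size() - 1;
}

void join_sweep(Cdbg& D) {
  int k = D.k;
  std::deque<int> q;
  for (size_t i = 0; i < D.U.size(); ++i) if (D.U[i].live) q.push_back((int)i);
  while (!q.empty()) {
    int id = q.front(); q.pop_front();
    if (id >= (int)D.U.size() || !D.U[(size_t)id].live) continue;
    bool merged = true;
    while (merged) {
      merged = false;
      for (int ori = 0; ori < 2 && !merged; ++ori) {
        bool fwd = ori == 0;
        std::string so = D.oriented(id, fwd);
        std::string tail = so.substr(so.size() - (size_t)k);
        LookupHit hv; std::string sstr;
        if (graph_succ_count(D, tail, &hv, &sstr) != 1) continue;
        if (hv.id == id) continue; // circular unitig
        if (graph_pred_count(D, sstr) != 1) continue;
        const Unitig& v = D.U[(size_t)hv.id];
        int vlen = (int)v.seq.size();
        bool vfwd;
        if (hv.forward && hv.offset == 0) vfwd = true;
        else if (!hv.forward && hv.offset == vlen - k) vfwd = false;
        else continue; // successor is not a terminal k-mer of v
        size_t ueta = so.size() - (size_t)k + 1;
        size_t veta = (size_t)(vlen - k + 1);
        // oriented payloads of u
        std::vector<uint8_t> uc = D.U[(size_t)id].counters;
        std::vector<std::pair<uint32_t, uint32_t> > ucp = unitig_color_pairs(D, id);
        if (!fwd) {
          std::reverse(uc.begin(), uc.end());
          for (auto& cp : ucp) cp.first = (uint32_t)(ueta - 1) - cp.first;
        }
        // oriented payloads of v
        std::string vseq = D.oriented(hv.id, vfwd);
        std::vector<uint8_t> vc = v.counters;
        std::vector<std::pair<uint32_t, uint32_t> > vcp = unitig_color_pairs(D, hv.id);
        if (!vfwd) {
          std::reverse(vc.begin(), vc.end());
          for (auto& cp : vcp) cp.first = (uint32_t)(veta - 1) - cp.first;
        }
        std::string mseq = so + vseq.substr((size_t)(k - 1));
        std::vector<uint8_t> mc = uc;
        mc.insert(mc.end(), vc.begin(), vc.end());
        std::vector<std::pair<uint32_t, uint32_t> > mcp = ucp;
        for (auto& cp : vcp)
          mcp.push_back(std::make_pair(cp.first + (uint32_t)ueta, cp.second));
        D.remove_unitig(id);
        D.remove_unitig(hv.id);
        id = insert_oriented(D, mseq, mc, mcp);
        ++D.n_joins;
        merged = true;
      }
    }
  }
}

void split_at_branches(Cdbg& D) {
  int k = D.k;
  std::vector<int> ids;
  for (size_t i = 0; i < D.U.size(); ++i) if (D.U[i].live) ids.push_back((int)i);
  for (int id : ids) {
    if (!D.U[(size_t)id].live) continue;
    const std::string& seq = D.U[(size_t)id].seq;
    int eta = (int)seq.size() - k + 1;
    if (eta < 2) continue;
    std::vector<int> cut; // cut between k-mer i and i+1
    for (int i = 0; i + 1 < eta; ++i) {
      std::string x = seq.substr((size_t)i, (size_t)k);
      std::string y = seq.substr((size_t)(i + 1), (size_t)k);
      if (graph_succ_count(D, x, nullptr, nullptr) > 1 ||
          graph_pred_count(D, y) > 1)
        cut.push_back(i);
    }
    if (cut.empty()) continue;
    std::vector<std::pair<int, int> > keep;
    int a = 0;
    for (int c : cut) { keep.push_back(std::make_pair(a, c)); a = c + 1; }
    keep.push_back(std::make_pair(a, eta - 1));
    split_unitig(D, id, keep);
  }
}

// ---------------------------------------------------------------------------
// false-positive elimination (counter threshold, split, then join to a
// fixed point)
// ---------------------------------------------------------------------------

void eliminate_fp(Cdbg& D, int threshold) {
  std::vector<int> ids;
  for (size_t i = 0; i < D.U.size(); ++i) if (D.U[i].live) ids.push_back((int)i);
  for (int id : ids) {
    const Unitig& u = D.U[(size_t)id];
    int eta = (int)u.seq.size() - D.k + 1;
    std::vector<std::pair<int, int> > keep;
    int a = -1, n_del = 0;
    for (int i = 0; i < eta; ++i) {
      if ((int)u.counters[(size_t)i] >= threshold) {
        if (a < 0) a = i;
      } else {
        ++n_del;
        if (a >= 0) keep.push_back(std::make_pair(a, i - 1));
        a = -1;
      }
    }
    if (a == 0 && n_del == 0) continue; // nothing below threshold
    if (a >= 0) keep.push_back(std::make_pair(a, eta - 1));
    D.n_fp_deleted += (uint64_t)n_del;
    split_unitig(D, id, keep);
  }
  join_sweep(D);
}

// ---------------------------------------------------------------------------
// node-centric dynamic update: insert new k-mers, restore maximal
// compaction by splitting at new branch points and re-joining
// ---------------------------------------------------------------------------

void cdbg_update_kmers(Cdbg& D, const std::vector<uint64_t>& new_kmers) {
  int k = D.k;
  for (uint64_t c : new_kmers) {
    std::string s = decode_dna(c, k);
    if (D.lookup(s).found) continue;
    normalize_unitig(s);
    D.insert_unitig(s);
  }
  split_at_branches(D);
  join_sweep(D);
}

// ---------------------------------------------------------------------------
// Rcpp boundary
// ---------------------------------------------------------------------------

static Membership* membership_from(SEXP filter, std::unique_ptr<Membership>& holder) {
  RObject o(filter);
  if (o.inherits("bbf_ptr")) {
    XPtr<BBF> b(filter);
    holder.reset(new BbfMembership(b.get()));
    return holder.get();
  }
  if (o.inherits("exact_ptr")) {
    XPtr<ExactMembership> e(filter);
    e->n_queries = 0; e->n_hits = 0;
    return e.get();
  }
  stop("filter must be a BBF or an exact k-mer filter");
  return nullptr;
}

// [[Rcpp::export]]
SEXP cpp_exact_filter_new(CharacterVector kmers) {
  XPtr<ExactMembership> p(new ExactMembership(), true);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if (!valid_dna(s)) stop("non-ACGT symbol in k-mer");
    p->set.insert(canon_code(encode_dna(s, 0, (int)s.size()), (int)s.size()));
  }
  p.attr("class") = "exact_ptr";
  return p;
}

// [[Rcpp::export]]
LogicalVector cpp_neighbors_present(SEXP filter, std::string kmer, int g,
                                    double seed, std::string direction) {
  std::unique_ptr<Membership> holder;
  Membership* mb = membership_from(filter, holder);
  int k = (int)kmer.size();
  uint64_t fwd = encode_dna(kmer, 0, k);
  bool forward = direction == "forward";
  uint64_t maskk = mask_for(k);
  LogicalVector out(4);
  for (uint64_t a = 0; a < 4; ++a) {
    uint64_t nb = forward ? (((fwd << 2) | a) & maskk)
                          : ((a << (2 * (k - 1))) | (fwd >> 2));
    uint64_t c = canon_code(nb, k);
    uint64_t mh = min_interior_hash(nb, k, g, (uint64_t)seed);
    out[(R_xlen_t)a] = mb->query(c, mh);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_extract_unitig(SEXP filter, std::string kmer, int g, double seed,
                        bool use_ghosts, bool instrument) {
  std::unique_ptr<Membership> holder;
  Membership* mb = membership_from(filter, holder);
  int k = (int)kmer.size();
  if (!valid_dna(kmer)) stop("non-ACGT symbol in k-mer");
  uint64_t fwd = encode_dna(kmer, 0, k);
  uint64_t c = canon_code(fwd, k);
  uint64_t mh = minimizer_of_code(fwd, k, g, (uint64_t)seed).hash;
  if (!mb->query(c, mh)) stop("k-mer is not present in the filter");
  mb->n_queries = 0; mb->n_hits = 0;
  std::unordered_map<uint64_t, uint64_t> ghosts;
  ExtractInstr instr;
  std::string u = extract_unitig_core(*mb, fwd, k, g, (uint64_t)seed,
                                      use_ghosts ? &ghosts : nullptr, nullptr,
                                      instrument ? &instr : nullptr);
  CharacterVector gh((R_xlen_t)ghosts.size());
  R_xlen_t i = 0;
  for (const auto& kv : ghosts) gh[i++] = decode_dna(kv.first, k);
  return List::create(_["seq"] = u,
                      _["n_queries"] = (double)mb->n_queries,
                      _["n_hits"] = (double)mb->n_hits,
                      _["step_probes"] = wrap(instr.step_probes),
                      _["step_hits"] = wrap(instr.step_hits),
                      _["ghosts"] = gh);
}

// [[Rcpp::export]]
List cpp_build_pass(SEXP ptr, CharacterVector seqs, SEXP filter) {
  XPtr<Cdbg> D(ptr);
  std::unique_ptr<Membership> holder;
  Membership* mb = membership_from(filter, holder);
  std::vector<std::string> v;
  v.reserve((size_t)seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) v.push_back(as<std::string>(seqs[i]));
  build_pass(*D, *mb, v);
  return List::create(_["n_unitigs"] = (double)D->n_live,
                      _["n_ghosts"] = (double)D->ghosts.size(),
                      _["n_ghost_repairs"] = (double)D->n_ghost_repairs);
}

// [[Rcpp::export]]
List cpp_eliminate_fp(SEXP ptr, int threshold) {
  XPtr<Cdbg> D(ptr);
  eliminate_fp(*D, threshold);
  return List::create(_["n_fp_deleted"] = (double)D->n_fp_deleted,
                      _["n_splits"] = (double)D->n_splits,
                      _["n_joins"] = (double)D->n_joins,
                      _["n_unitigs"] = (double)D->n_live);
}

// [[Rcpp::export]]
List cpp_classify_fp(SEXP ptr, std::string kmer) {
  XPtr<Cdbg> D(ptr);
  LookupHit h = D->lookup(kmer);
  if (!h.found) stop("k-mer is not in the graph");
  int eta = (int)D->U[(size_t)h.id].seq.size() - D->k + 1;
  bool interior = h.offset > 0 && h.offset < eta - 1;
  return List::create(_["kind"] = interior ? "false_connection" : "false_branching",
                      _["id"] = h.id + 1, _["offset"] = h.offset + 1);
}

// [[Rcpp::export]]
List cpp_update_kmers(SEXP ptr, CharacterVector seqs) {
  XPtr<Cdbg> D(ptr);
  int k = D->k;
  std::vector<uint64_t> newk;
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (const auto& run : acgt_runs(s)) {
      if (run.second < (size_t)k) continue;
      for (size_t j = 0; j + (size_t)k <= run.second; ++j) {
        uint64_t c = canon_code(encode_dna(s, run.first + j, k), k);
        if (seen.count(c)) continue;
        seen.insert(c);
        if (!D->lookup(decode_dna(c, k)).found) newk.push_back(c);
      }
    }
  }
  cdbg_update_kmers(*D, newk);
  return List::create(_["n_new_kmers"] = (double)newk.size(),
                      _["n_unitigs"] = (double)D->n_live);
}

// premature-halt model for unitig extraction without ghost protection:
// each advance makes 6 probes that should return false; a false positive
// (probability p each) halts the extension. Returns extracted lengths in
// k-mers over independent trials.
// [[Rcpp::export]]
NumericVector cpp_simulate_halt_lengths(double n_trials, double p, int probes,
                                        double seed) {
  std::mt19937_64 rng((uint64_t)seed ^ 0x9E3779B9ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  R_xlen_t n = (R_xlen_t)n_trials;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double len = 1;
    for (;;) {
      bool halt = false;
      for (int j = 0; j < probes; ++j)
        if (unif(rng) < p) { halt = true; break; }
      if (halt) break;
      len += 1;
    }
    out[i] = len;
  }
  return out;
}
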