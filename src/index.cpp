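#include <Rcpp.h>
#include "cdbg.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Cdbg methods: D = (U, M)
// ---------------------------------------------------------------------------

MiniOcc Cdbg::select_insert_minimizer(const std::string& s, size_t pos,
                                      bool* fallback, bool* overflow) const {
  std::vector<MiniOcc> cand = interior_gmers(s, pos, k, g, seed);
  std::stable_sort(cand.begin(), cand.end(),
                   [](const MiniOcc& a, const MiniOcc& b) { return a.hash < b.hash; });
  if (fallback) *fallback = false;
  if (overflow) *overflow = false;
  for (size_t i = 0; i < cand.size(); ++i) {
    auto it = M.find(cand[i].gcode);
    bool recur = (it != M.end()) &&
                 (it->second.recurrent || (int)it->second.tuples.size() >= t);
    if (!recur) {
      if (fallback && i > 0) *fallback = true;
      return cand[i];
    }
  }
  if (overflow) *overflow = true; // every interior g-mer recurrent
  return cand[0];
}

int Cdbg::insert_unitig(const std::string& seq) {
  return insert_unitig_full(seq, nullptr, nullptr);
}

int Cdbg::insert_unitig_full(const std::string& seq, const std::vector<uint8_t>* ctr,
                             const std::vector<std::pair<uint32_t, uint32_t> >* color_pairs) {
  if ((int)seq.size() < k) throw std::runtime_error("unitig shorter than k");
  int id;
  if (!free_ids.empty()) { id = free_ids.back(); free_ids.pop_back(); }
  else { U.push_back(Unitig()); id = (int)U.size() - 1; }
  Unitig& u = U[(size_t)id];
  u.seq = seq;
  u.live = true;
  size_t eta = seq.size() - (size_t)k + 1;
  if (ctr) u.counters = *ctr; else u.counters.assign(eta, 0);
  u.color_slot = -1;
  u.mins.clear();
  ++n_live;

  std::set<std::pair<uint64_t, int> > seen; // dedup (gcode, pos) within this unitig
  for (size_t i = 0; i < eta; ++i) {
    MiniOcc sel = select_insert_minimizer(seq, i, nullptr, nullptr);
    int abs_pos = (int)i + sel.pos;
    std::pair<uint64_t, int> key(sel.gcode, abs_pos);
    if (seen.count(key)) continue;
    seen.insert(key);
    MinList& ml = M[sel.gcode];
    ml.tuples.push_back(std::make_pair(id, abs_pos));
    if ((int)ml.tuples.size() >= t) ml.recurrent = true;
    u.mins.push_back(std::make_pair(sel.gcode, abs_pos));
  }
  if (color_pairs && colors.active) {
    for (size_t q = 0; q < color_pairs->size(); ++q)
      color_add(*this, id, (*color_pairs)[q].first, (*color_pairs)[q].second);
  }
  return id;
}

void Cdbg::remove_unitig(int id) {
  if (id < 0 || id >= (int)U.size() || !U[(size_t)id].live)
    throw std::runtime_error("unknown or already removed unitig id");
  Unitig& u = U[(size_t)id];
  for (size_t q = 0; q < u.mins.size(); ++q) {
    auto it = M.find(u.mins[q].first);
    if (it == M.end()) continue;
    auto& tu = it->second.tuples;
    for (size_t j = 0; j < tu.size(); ++j) {
      if (tu[j].first == id && tu[j].second == u.mins[q].second) {
        tu.erase(tu.begin() + (std::ptrdiff_t)j);
        break;
      }
    }
    if (tu.empty() && !it->second.recurrent) M.erase(it);
  }
  if (u.color_slot >= 0) release_slot(*this, id);
  u.seq.clear();
  u.counters.clear();
  u.mins.clear();
  u.live = false;
  --n_live;
  free_ids.push_back(id);
}

LookupHit Cdbg::lookup(const std::string& kmer) const {
  LookupHit miss;
  if ((int)kmer.size() != k || !valid_dna(kmer)) return miss;
  std::vector<MiniOcc> occ = interior_gmers(kmer, 0, k, g, seed);
  // group occurrences by g-mer, candidates in ascending hash order
  std::stable_sort(occ.begin(), occ.end(),
                   [](const MiniOcc& a, const MiniOcc& b) { return a.hash < b.hash; });
  std::string rc = revcomp_str(kmer);
  size_t i = 0;
  while (i < occ.size()) {
    uint64_t gc = occ[i].gcode;
    size_t jend = i;
    std::vector<int> qs;
    while (jend < occ.size() && occ[jend].gcode == gc) { qs.push_back(occ[jend].pos); ++jend; }
    auto it = M.find(gc);
    bool recur = false;
    if (it != M.end()) {
      recur = it->second.recurrent || (int)it->second.tuples.size() >= t;
      for (const auto& tup : it->second.tuples) {
        const Unitig& u = U[(size_t)tup.first];
        if (!u.live) continue;
        for (int q : qs) {
          int off = tup.second - q;
          if (off >= 0 && off + k <= (int)u.seq.size() &&
              u.seq.compare((size_t)off, (size_t)k, kmer) == 0) {
            LookupHit h; h.found = true; h.id = tup.first; h.offset = off; h.forward = true;
            return h;
          }
          int qr = k - g - q;
          int offr = tup.second - qr;
          if (offr >= 0 && offr + k <= (int)u.seq.size() &&
              u.seq.compare((size_t)offr, (size_t)k, rc) == 0) {
            LookupHit h; h.found = true; h.id = tup.first; h.offset = offr; h.forward = false;
            return h;
          }
        }
      }
    }
    if (!recur) return miss; // non-recurrent minimizer exhausted: k-mer absent
    i = jend; // recurrent: continue with the next minimizer of x
  }
  return miss;
}

LookupHit Cdbg::lookup_code(uint64_t /*canon*/, uint64_t fwd) const {
  return lookup(decode_dna(fwd, k));
}

// ---------------------------------------------------------------------------
// Rcpp exports: k-mer arithmetic
// ---------------------------------------------------------------------------

static std::string check_dna(const std::string& s, const char* what) {
  if (!valid_dna(s)) stop("%s contains a non-ACGT symbol: '%s'", what, s.c_str());
  return s;
}

static std::string hash_hex(uint64_t h) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector s) {
  CharacterVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i)
    out[i] = revcomp_str(check_dna(as<std::string>(s[i]), "sequence"));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector s) {
  CharacterVector out(s.size());
  for (R_xlen_t i = 0; i < s.size(); ++i)
    out[i] = canonical_str(check_dna(as<std::string>(s[i]), "sequence"));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_gmer_hash(CharacterVector gmers, double seed) {
  uint64_t sd = (uint64_t)seed;
  CharacterVector out(gmers.size());
  for (R_xlen_t i = 0; i < gmers.size(); ++i) {
    std::string s = check_dna(as<std::string>(gmers[i]), "g-mer");
    if (s.size() > 31) stop("g-mer longer than 31 bases");
    uint64_t code = canon_code(encode_dna(s, 0, (int)s.size()), (int)s.size());
    out[i] = hash_hex(gmer_hash_code(code, sd));
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_minimizer_of(CharacterVector kmers, int g, double seed) {
  uint64_t sd = (uint64_t)seed;
  R_xlen_t n = kmers.size();
  CharacterVector gm(n), hh(n);
  IntegerVector pos(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = check_dna(as<std::string>(kmers[i]), "k-mer");
    int k = (int)s.size();
    if (g < 1 || g > k - 2) stop("g must satisfy 1 <= g <= k - 2");
    MiniOcc m = minimizer_of_kmer(s, 0, k, g, sd);
    gm[i] = decode_dna(m.gcode, g);
    hh[i] = hash_hex(m.hash);
    pos[i] = m.pos + 1; // 1-based at the R boundary
  }
  return DataFrame::create(_["gmer"] = gm, _["hash"] = hh, _["pos"] = pos,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_iterate_minimizers(std::string seq, int k, int g, double seed) {
  uint64_t sd = (uint64_t)seed;
  check_dna(seq, "sequence");
  if (g < 1 || g > k - 2) stop("g must satisfy 1 <= g <= k - 2");
  std::vector<MiniOcc> ms = run_minimizers(seq, k, g, sd);
  R_xlen_t n = (R_xlen_t)ms.size();
  IntegerVector idx(n), pos(n), pos_abs(n);
  CharacterVector gm(n), hh(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    idx[i] = (int)i + 1;
    gm[i] = decode_dna(ms[(size_t)i].gcode, g);
    hh[i] = hash_hex(ms[(size_t)i].hash);
    pos_abs[i] = ms[(size_t)i].pos + 1;
    pos[i] = ms[(size_t)i].pos - (int)i + 1; // within the i-th k-mer
  }
  return DataFrame::create(_["kmer_index"] = idx, _["gmer"] = gm, _["hash"] = hh,
                           _["pos"] = pos, _["pos_abs"] = pos_abs,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Rcpp exports: cdBG dictionary
// ---------------------------------------------------------------------------

static Cdbg* get_cdbg(SEXP ptr) {
  XPtr<Cdbg> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_cdbg_new(int k, int g, int t, double seed) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  if (g < 1 || g > k - 2) stop("g must satisfy 1 <= g <= k - 2");
  if (t < 1) stop("t must be >= 1");
  XPtr<Cdbg> p(new Cdbg(k, g, t, (uint64_t)seed), true);
  p.attr("class") = "cdbg_ptr";
  return p;
}

// [[Rcpp::export]]
List cpp_cdbg_params(SEXP ptr) {
  Cdbg* D = get_cdbg(ptr);
  return List::create(_["k"] = D->k, _["g"] = D->g, _["t"] = D->t,
                      _["seed"] = (double)D->seed);
}

// [[Rcpp::export]]
int cpp_insert_unitig(SEXP ptr, std::string seq) {
  Cdbg* D = get_cdbg(ptr);
  check_dna(seq, "unitig");
  return D->insert_unitig(seq) + 1;
}

// [[Rcpp::export]]
void cpp_remove_unitig(SEXP ptr, int id) {
  get_cdbg(ptr)->remove_unitig(id - 1);
}

// [[Rcpp::export]]
DataFrame cpp_lookup_kmers(SEXP ptr, CharacterVector kmers) {
  Cdbg* D = get_cdbg(ptr);
  R_xlen_t n = kmers.size();
  LogicalVector found(n);
  IntegerVector id(n), offset(n);
  CharacterVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    LookupHit h = D->lookup(s);
    found[i] = h.found;
    if (h.found) {
      id[i] = h.id + 1;
      offset[i] = h.offset + 1;
      strand[i] = h.forward ? "forward" : "reverse";
    } else {
      id[i] = NA_INTEGER; offset[i] = NA_INTEGER; strand[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["kmer"] = kmers, _["found"] = found, _["id"] = id,
                           _["offset"] = offset, _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_unitigs(SEXP ptr) {
  Cdbg* D = get_cdbg(ptr);
  std::vector<int> ids;
  for (size_t i = 0; i < D->U.size(); ++i) if (D->U[i].live) ids.push_back((int)i);
  R_xlen_t n = (R_xlen_t)ids.size();
  IntegerVector id(n), nk(n);
  CharacterVector seq(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const Unitig& u = D->U[(size_t)ids[(size_t)i]];
    id[i] = ids[(size_t)i] + 1;
    seq[i] = u.seq;
    nk[i] = (int)(u.seq.size()) - D->k + 1;
  }
  return DataFrame::create(_["id"] = id, _["seq"] = seq, _["n_kmers"] = nk,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_cdbg_stats(SEXP ptr) {
  Cdbg* D = get_cdbg(ptr);
  return List::create(_["n_unitigs"] = (double)D->n_live,
                      _["n_kmers"] = (double)D->n_kmers(),
                      _["n_minimizer_keys"] = (double)D->M.size(),
                      _["n_ghosts"] = (double)D->ghosts.size(),
                      _["n_ghost_repairs"] = (double)D->n_ghost_repairs,
                      _["n_fp_deleted"] = (double)D->n_fp_deleted,
                      _["n_splits"] = (double)D->n_splits,
                      _["n_joins"] = (double)D->n_joins);
}

// [[Rcpp::export]]
List cpp_select_insert_minimizer(SEXP ptr, std::string kmer) {
  Cdbg* D = get_cdbg(ptr);
  check_dna(kmer, "k-mer");
  if ((int)kmer.size() != D->k) stop("k-mer length does not match the graph's k");
  bool fb = false, ov = false;
  MiniOcc m = D->select_insert_minimizer(kmer, 0, &fb, &ov);
  return List::create(_["gmer"] = decode_dna(m.gcode, D->g),
                      _["hash"] = hash_hex(m.hash), _["pos"] = m.pos + 1,
                      _["fallback"] = fb, _["overflow"] = ov);
}

// [[Rcpp::export]]
DataFrame cpp_minimizer_table(SEXP ptr) {
  Cdbg* D = get_cdbg(ptr);
  std::vector<std::string> gm;
  std::vector<int> id, pos;
  std::vector<bool> rec;
  for (const auto& kv : D->M) {
    for (const auto& tup : kv.second.tuples) {
      gm.push_back(decode_dna(kv.first, D->g));
      id.push_back(tup.first + 1);
      pos.push_back(tup.second + 1);
      rec.push_back(kv.second.recurrent);
    }
  }
  return DataFrame::create(_["gmer"] = gm, _["id"] = id, _["pos"] = pos,
                           _["recurrent"] = rec, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
IntegerVector cpp_counters(SEXP ptr, int id) {
  Cdbg* D = get_cdbg(ptr);
  if (id < 1 || id > (int)D->U.size() || !D->U[(size_t)(id - 1)].live)
    stop("unknown unitig id");
  const std::vector<uint8_t>& c = D->U[(size_t)(id - 1)].counters;
  IntegerVector out((R_xlen_t)c.size());
  for (size_t i = 0; i < c.size(); ++i) out[(R_xlen_t)i] = c[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_ghosts(SEXP ptr) {
  Cdbg* D = get_cdbg(ptr);
  CharacterVector out((R_xlen_t)D->ghosts.size());
  R_xlen_t i = 0;
  for (const auto& kv : D->ghosts) out[i++] = decode_dna(kv.first, D->k);
  return out;
}
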