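#include <Rcpp.h>
#include "cdbg.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// slot assignment (array O of containers, seed array H, fallback table K)
// ---------------------------------------------------------------------------

static uint64_t head_kmer_code(const Cdbg& D, int id) {
  const Unitig& u = D.U[(size_t)id];
  return canon_code(encode_dna(u.seq, 0, D.k), D.k);
}

int assign_slot(Cdbg& D, int id) {
  ColorStore& cs = D.colors;
  if (!cs.active) throw std::runtime_error("color store not initialised");
  Unitig& u = D.U[(size_t)id];
  if (u.color_slot >= 0) return u.color_slot;
  if (4 * (cs.n_claimed + 1) > 3 * cs.O.size()) { // keep load under 3/4
    size_t old = cs.O.size();
    cs.O.resize(old * 2);
    cs.claimed.resize(old * 2, 0);
  }
  uint64_t hc = head_kmer_code(D, id);
  for (size_t r = 0; r < cs.H.size(); ++r) {
    uint64_t s = splitmix64(hc ^ cs.H[r]) % cs.O.size();
    if (!cs.claimed[s]) {
      cs.claimed[s] = 1;
      ++cs.n_claimed;
      u.color_slot = (int)s;
      return (int)s;
    }
  }
  // all seeds collided: append a fresh slot and remember it in K
  cs.O.push_back(ColorContainer());
  cs.claimed.push_back(1);
  ++cs.n_claimed;
  int s = (int)cs.O.size() - 1;
  cs.K[hc] = s;
  ++cs.n_fallback;
  u.color_slot = s;
  return s;
}

void release_slot(Cdbg& D, int id) {
  ColorStore& cs = D.colors;
  Unitig& u = D.U[(size_t)id];
  if (u.color_slot < 0) return;
  cs.O[(size_t)u.color_slot].clear();
  cs.claimed[(size_t)u.color_slot] = 0;
  --cs.n_claimed;
  auto it = cs.K.find(head_kmer_code(D, id));
  if (it != cs.K.end() && it->second == u.color_slot) cs.K.erase(it);
  u.color_slot = -1;
}

void color_add(Cdbg& D, int id, uint32_t row, uint32_t col) {
  ColorStore& cs = D.colors;
  Unitig& u = D.U[(size_t)id];
  uint64_t eta = u.seq.size() - (size_t)D.k + 1;
  uint64_t nc = cs.color_names.size();
  if (row >= eta) throw std::runtime_error("color row out of range");
  if (col >= nc) throw std::runtime_error("color index out of range");
  int slot = u.color_slot >= 0 ? u.color_slot : assign_slot(D, id);
  cs.O[(size_t)slot].add(row, col, eta, nc);
}

void register_color(Cdbg& D, const std::string& name) {
  ColorStore& cs = D.colors;
  uint64_t old_nc = cs.color_names.size();
  cs.color_names.push_back(name);
  uint64_t new_nc = cs.color_names.size();
  if (old_nc == 0) return;
  // bit-matrix payloads are laid out row*|C|+col: re-encode on |C| change
  for (size_t i = 0; i < D.U.size(); ++i) {
    const Unitig& u = D.U[i];
    if (!u.live || u.color_slot < 0) continue;
    uint64_t eta = u.seq.size() - (size_t)D.k + 1;
    cs.O[(size_t)u.color_slot].rebase_ncolors(eta, old_nc, new_nc);
  }
}

std::vector<std::pair<uint32_t, uint32_t> > unitig_color_pairs(const Cdbg& D, int id) {
  std::vector<std::pair<uint32_t, uint32_t> > out;
  const Unitig& u = D.U[(size_t)id];
  if (!D.colors.active || u.color_slot < 0) return out;
  uint64_t eta = u.seq.size() - (size_t)D.k + 1;
  return D.colors.O[(size_t)u.color_slot].all_pairs(eta, D.colors.color_names.size());
}

// ---------------------------------------------------------------------------
// Rcpp exports
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
void cpp_init_colors(SEXP ptr, CharacterVector names, int n_seeds) {
  XPtr<Cdbg> D(ptr);
  D->colors.init(D->seed, n_seeds);
  for (R_xlen_t i = 0; i < names.size(); ++i)
    register_color(*D, as<std::string>(names[i]));
}

// [[Rcpp::export]]
int cpp_register_color(SEXP ptr, std::string name) {
  XPtr<Cdbg> D(ptr);
  if (!D->colors.active) D->colors.init(D->seed, 16);
  register_color(*D, name);
  return (int)D->colors.color_names.size();
}

// [[Rcpp::export]]
CharacterVector cpp_color_names(SEXP ptr) {
  XPtr<Cdbg> D(ptr);
  return wrap(D->colors.color_names);
}

// streams the k-mers of one color's sequences; k-mers absent from the
// graph are skipped (reads mode: they were filtered) or raise (strict)
// [[Rcpp::export]]
List cpp_add_color_file(SEXP ptr, CharacterVector seqs, int color, bool strict) {
  XPtr<Cdbg> D(ptr);
  if (!D->colors.active) stop("color store not initialised");
  if (color < 1 || color > (int)D->colors.color_names.size()) stop("unknown color index");
  int k = D->k;
  double n_set = 0, n_skipped = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (const auto& run : acgt_runs(s)) {
      if (run.second < (size_t)k) continue;
      for (size_t j = 0; j + (size_t)k <= run.second; ++j) {
        std::string km = s.substr(run.first + j, (size_t)k);
        LookupHit h = D->lookup(km);
        if (!h.found) {
          if (strict) stop("k-mer '%s' of color %d is absent from the graph", km.c_str(), color);
          n_skipped += 1;
          continue;
        }
        color_add(*D, h.id, (uint32_t)h.offset, (uint32_t)(color - 1));
        n_set += 1;
      }
    }
  }
  return List::create(_["n_set"] = n_set, _["n_skipped"] = n_skipped);
}

// [[Rcpp::export]]
List cpp_colors_of(SEXP ptr, CharacterVector kmers) {
  XPtr<Cdbg> D(ptr);
  uint64_t nc = D->colors.color_names.size();
  List out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    LookupHit h = D->lookup(s);
    if (!h.found) { out[i] = R_NilValue; continue; }
    const Unitig& u = D->U[(size_t)h.id];
    std::vector<int> cols;
    if (u.color_slot >= 0) {
      uint64_t eta = u.seq.size() - (size_t)D->k + 1;
      const ColorContainer& cc = D->colors.O[(size_t)u.color_slot];
      for (uint64_t j = 0; j < nc; ++j)
        if (cc.has((uint32_t)h.offset, (uint32_t)j, nc)) cols.push_back((int)j + 1);
    }
    out[i] = wrap(cols);
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_unitig_colors(SEXP ptr, int id) {
  XPtr<Cdbg> D(ptr);
  if (id < 1 || id > (int)D->U.size() || !D->U[(size_t)(id - 1)].live)
    stop("unknown unitig id");
  auto pairs = unitig_color_pairs(*D, id - 1);
  IntegerVector row((R_xlen_t)pairs.size()), col((R_xlen_t)pairs.size());
  for (size_t i = 0; i < pairs.size(); ++i) {
    row[(R_xlen_t)i] = (int)pairs[i].first + 1;
    col[(R_xlen_t)i] = (int)pairs[i].second + 1;
  }
  return DataFrame::create(_["row"] = row, _["color"] = col);
}

// singleton / core / dispensable partition and the fraction of unitigs
// whose k-mers all share one color set
// [[Rcpp::export]]
List cpp_color_summary(SEXP ptr) {
  XPtr<Cdbg> D(ptr);
  uint64_t nc = D->colors.color_names.size();
  double singleton = 0, core = 0, dispensable = 0, uncolored = 0;
  double n_unitigs = 0, single_set = 0;
  for (size_t idx = 0; idx < D->U.size(); ++idx) {
    const Unitig& u = D->U[idx];
    if (!u.live) continue;
    n_unitigs += 1;
    uint64_t eta = u.seq.size() - (size_t)D->k + 1;
    std::vector<std::vector<int> > rows((size_t)eta);
    if (u.color_slot >= 0) {
      const ColorContainer& cc = D->colors.O[(size_t)u.color_slot];
      for (const auto& pr : cc.all_pairs(eta, nc)) rows[pr.first].push_back((int)pr.second);
    }
    bool same = true;
    for (size_t i = 0; i < (size_t)eta; ++i) {
      std::sort(rows[i].begin(), rows[i].end());
      size_t m = rows[i].size();
      if (m == 0) uncolored += 1;
      else if (m == 1) singleton += 1;
      else if (m == nc) core += 1;
      else dispensable += 1;
      if (i > 0 && rows[i] != rows[0]) same = false;
    }
    if (same) single_set += 1;
  }
  return List::create(_["n_colors"] = (double)nc,
                      _["singleton"] = singleton, _["core"] = core,
                      _["dispensable"] = dispensable, _["uncolored"] = uncolored,
                      _["frac_single_set_unitigs"] = n_unitigs > 0 ? single_set / n_unitigs : NA_REAL);
}

// [[Rcpp::export]]
List cpp_color_store_info(SEXP ptr) {
  XPtr<Cdbg> D(ptr);
  const ColorStore& cs = D->colors;
  return List::create(_["active"] = cs.active,
                      _["n_slots"] = (double)cs.O.size(),
                      _["n_claimed"] = (double)cs.n_claimed,
                      _["n_seeds"] = (double)cs.H.size(),
                      _["n_fallback"] = (double)cs.K.size());
}

// [[Rcpp::export]]
int cpp_slot_of(SEXP ptr, int id) {
  XPtr<Cdbg> D(ptr);
  if (id < 1 || id > (int)D->U.size() || !D->U[(size_t)(id - 1)].live)
    stop("unknown unitig id");
  return D->U[(size_t)(id - 1)].color_slot + 1; // 0 = unassigned
}

// [[Rcpp::export]]
int cpp_assign_slot(SEXP ptr, int id) {
  XPtr<Cdbg> D(ptr);
  return assign_slot(*D, id - 1) + 1;
}

// ---------------------------------------------------------------------------
// standalone container handles for tier-boundary testing
// ---------------------------------------------------------------------------

struct CcHandle {
  ColorContainer cc;
  uint64_t eta, nc;
};

// [[Rcpp::export]]
SEXP cpp_cc_new(double eta, double ncolors) {
  XPtr<CcHandle> p(new CcHandle(), true);
  p->eta = (uint64_t)eta;
  p->nc = (uint64_t)ncolors;
  p.attr("class") = "cc_ptr";
  return p;
}

// [[Rcpp::export]]
void cpp_cc_add(SEXP ptr, IntegerVector i, IntegerVector j) {
  XPtr<CcHandle> p(ptr);
  for (R_xlen_t q = 0; q < i.size(); ++q) {
    if (i[q] < 1 || (uint64_t)i[q] > p->eta) stop("row out of range");
    if (j[q] < 1 || (uint64_t)j[q] > p->nc) stop("color out of range");
    p->cc.add((uint32_t)(i[q] - 1), (uint32_t)(j[q] - 1), p->eta, p->nc);
  }
}

// [[Rcpp::export]]
LogicalVector cpp_cc_has(SEXP ptr, IntegerVector i, IntegerVector j) {
  XPtr<CcHandle> p(ptr);
  LogicalVector out(i.size());
  for (R_xlen_t q = 0; q < i.size(); ++q)
    out[q] = p->cc.has((uint32_t)(i[q] - 1), (uint32_t)(j[q] - 1), p->nc);
  return out;
}

// [[Rcpp::export]]
std::string cpp_cc_tier(SEXP ptr) {
  XPtr<CcHandle> p(ptr);
  switch (p->cc.tier) {
    case 0: return "word";
    case 1: return "medium";
    default: return "large";
  }
}

// [[Rcpp::export]]
DataFrame cpp_cc_pairs(SEXP ptr) {
  XPtr<CcHandle> p(ptr);
  auto pr = p->cc.all_pairs(p->eta, p->nc);
  IntegerVector i((R_xlen_t)pr.size()), j((R_xlen_t)pr.size());
  for (size_t q = 0; q < pr.size(); ++q) {
    i[(R_xlen_t)q] = (int)pr[q].first + 1;
    j[(R_xlen_t)q] = (int)pr[q].second + 1;
  }
  return DataFrame::create(_["row"] = i, _["color"] = j);
}
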