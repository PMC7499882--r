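#include <Rcpp.h>
#include "cdbg.h"
#include <tuple>
using namespace Rcpp;

// all canonical k-mers within one substitution or one windowed indel of x:
// a deletion drops one base and restores length k by appending a base at
// either window edge; an insertion adds one base and trims one base from
// either edge. x itself is included.
static std::vector<std::string> edit1_variants_str(const std::string& x) {
  int k = (int)x.size();
  std::set<std::string> out;
  out.insert(canonical_str(x));
  // substitutions
  for (int p = 0; p < k; ++p) {
    std::string y = x;
    for (int a = 0; a < 4; ++a) {
      char c = code_base(a);
      if (c == x[(size_t)p]) continue;
      y[(size_t)p] = c;
      out.insert(canonical_str(y));
    }
  }
  // deletion + one appended base on either end
  for (int d = 0; d < k; ++d) {
    std::string core = x.substr(0, (size_t)d) + x.substr((size_t)d + 1);
    for (int a = 0; a < 4; ++a) {
      char c = code_base(a);
      out.insert(canonical_str(c + core));
      out.insert(canonical_str(core + c));
    }
  }
  // insertion + one trimmed base on either end
  for (int p = 0; p <= k; ++p) {
    for (int a = 0; a < 4; ++a) {
      std::string y = x.substr(0, (size_t)p) + std::string(1, code_base(a)) +
                      x.substr((size_t)p);
      out.insert(canonical_str(y.substr(0, (size_t)k)));
      out.insert(canonical_str(y.substr(1, (size_t)k)));
    }
  }
  return std::vector<std::string>(out.begin(), out.end());
}

// [[Rcpp::export]]
CharacterVector cpp_edit1_variants(std::string kmer) {
  if (!valid_dna(kmer)) stop("non-ACGT symbol in k-mer");
  return wrap(edit1_variants_str(kmer));
}

// [[Rcpp::export]]
List cpp_query_sequences(SEXP ptr, CharacterVector seqs, double theta,
                         bool inexact, bool report_colors) {
  XPtr<Cdbg> D(ptr);
  int k = D->k;
  uint64_t nc = D->colors.color_names.size();
  R_xlen_t n = seqs.size();
  IntegerVector n_kmers(n), n_found(n);
  NumericVector ratio(n);
  LogicalVector present(n), too_short(n);
  NumericMatrix colmat(report_colors ? n : 0, report_colors ? (R_xlen_t)nc : 0);
  for (R_xlen_t qi = 0; qi < n; ++qi) {
    std::string s = as<std::string>(seqs[qi]);
    int nk = 0, nf = 0;
    std::vector<double> ccount((size_t)nc, 0.0);
    for (const auto& run : acgt_runs(s)) {
      if (run.second < (size_t)k) continue;
      for (size_t j = 0; j + (size_t)k <= run.second; ++j) {
        ++nk;
        std::string km = s.substr(run.first + j, (size_t)k);
        LookupHit h = D->lookup(km);
        if (!h.found && inexact) {
          for (const std::string& v : edit1_variants_str(km)) {
            h = D->lookup(v);
            if (h.found) break;
          }
        }
        if (!h.found) continue;
        ++nf;
        if (report_colors && D->colors.active) {
          const Unitig& u = D->U[(size_t)h.id];
          if (u.color_slot >= 0) {
            uint64_t eta = u.seq.size() - (size_t)k + 1;
            const ColorContainer& cc = D->colors.O[(size_t)u.color_slot];
            for (uint64_t c = 0; c < nc; ++c)
              if (cc.has((uint32_t)h.offset, (uint32_t)c, nc)) ccount[(size_t)c] += 1;
          }
        }
      }
    }
    n_kmers[qi] = nk;
    n_found[qi] = nf;
    too_short[qi] = nk == 0;
    ratio[qi] = nk > 0 ? (double)nf / nk : 0.0;
    present[qi] = nk > 0 && ratio[qi] >= theta;
    if (report_colors)
      for (uint64_t c = 0; c < nc; ++c)
        colmat(qi, (R_xlen_t)c) = nk > 0 ? ccount[(size_t)c] / nk : 0.0;
  }
  return List::create(_["n_kmers"] = n_kmers, _["n_found"] = n_found,
                      _["ratio"] = ratio, _["present"] = present,
                      _["too_short"] = too_short, _["colors"] = colmat);
}

// directed unitig adjacencies for GFA export: one row per link, emitted
// from the source orientation in which the k-1 overlap holds
// [[Rcpp::export]]
DataFrame cpp_adjacency(SEXP ptr) {
  XPtr<Cdbg> D(ptr);
  int k = D->k;
  std::set<std::tuple<int, char, int, char> > links;
  for (size_t i = 0; i < D->U.size(); ++i) {
    if (!D->U[i].live) continue;
    for (int ori = 0; ori < 2; ++ori) {
      bool fwd = ori == 0;
      std::string so = D->oriented((int)i, fwd);
      std::string tail = so.substr(so.size() - (size_t)k);
      std::string cand = tail.substr(1) + "A";
      for (int a = 0; a < 4; ++a) {
        cand[(size_t)k - 1] = code_base(a);
        LookupHit h = D->lookup(cand);
        if (!h.found) continue;
        int vlen = (int)D->U[(size_t)h.id].seq.size();
        char ov;
        if (h.forward && h.offset == 0) ov = '+';
        else if (!h.forward && h.offset == vlen - k) ov = '-';
        else continue;
        char ou = fwd ? '+' : '-';
        // a link and its reverse complement are the same edge
        std::tuple<int, char, int, char> e((int)i, ou, h.id, ov);
        std::tuple<int, char, int, char> er(h.id, ov == '+' ? '-' : '+',
                                            (int)i, ou == '+' ? '-' : '+');
        links.insert(std::min(e, er));
      }
    }
  }
  R_xlen_t m = (R_xlen_t)links.size();
  IntegerVector from(m), to(m);
  CharacterVector fo(m), to_o(m);
  R_xlen_t q = 0;
  for (const auto& e : links) {
    from[q] = std::get<0>(e) + 1;
    fo[q] = std::string(1, std::get<1>(e));
    to[q] = std::get<2>(e) + 1;
    to_o[q] = std::string(1, std::get<3>(e));
    ++q;
  }
  return DataFrame::create(_["from"] = from, _["from_orient"] = fo,
                           _["to"] = to, _["to_orient"] = to_o,
                           _["stringsAsFactors"] = false);
}
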