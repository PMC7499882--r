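#include <Rcpp.h>
#include "bbf.h"
#include <random>
using namespace Rcpp;

// [[Rcpp::export]]
double cpp_optimal_f(double m, double n) {
  double f = std::lround((m / n) * std::log(2.0));
  return f < 1 ? 1 : f;
}

// [[Rcpp::export]]
List cpp_expected_fpr(double m, double n, double f) {
  double phi = std::pow(1.0 - std::exp(-f * n / m), f);
  double approx = std::pow(0.7, m / n);
  // an absent element is tested against both candidate blocks, so the
  // blocked 2-choice filter misreports when either block fires
  double two_choice = 1.0 - (1.0 - phi) * (1.0 - phi);
  return List::create(_["phi"] = phi, _["approx"] = approx,
                      _["two_choice"] = two_choice);
}

// [[Rcpp::export]]
SEXP cpp_bbf_new(double n_expected, double bits_per_kmer, double seed, bool two_choice) {
  XPtr<BBF> p(new BBF(n_expected, bits_per_kmer, (uint64_t)seed, two_choice), true);
  p.attr("class") = "bbf_ptr";
  return p;
}

// [[Rcpp::export]]
List cpp_bbf_params(SEXP ptr) {
  XPtr<BBF> b(ptr);
  return List::create(_["nb_blocks"] = (double)b->nb_blocks,
                      _["block_bits"] = (int)BBF::BLOCK_BITS,
                      _["m"] = (double)(b->nb_blocks * BBF::BLOCK_BITS),
                      _["f"] = b->f,
                      _["total_set_bits"] = (double)b->total_set_bits());
}

// [[Rcpp::export]]
IntegerVector cpp_bbf_occupancy(SEXP ptr) {
  XPtr<BBF> b(ptr);
  IntegerVector out((R_xlen_t)b->occ.size());
  for (size_t i = 0; i < b->occ.size(); ++i) out[(R_xlen_t)i] = (int)b->occ[i];
  return out;
}

static void kmer_and_minhash(const std::string& s, int k, int g, uint64_t seed,
                             uint64_t* canon, uint64_t* minhash) {
  if ((int)s.size() != k) stop("k-mer length mismatch");
  if (!valid_dna(s)) stop("non-ACGT symbol in k-mer '%s'", s.c_str());
  uint64_t fwd = encode_dna(s, 0, k);
  *canon = canon_code(fwd, k);
  *minhash = minimizer_of_kmer(s, 0, k, g, seed).hash;
}

// [[Rcpp::export]]
IntegerVector cpp_bbf_insert(SEXP ptr, CharacterVector kmers, int g, double seed) {
  XPtr<BBF> b(ptr);
  uint64_t sd = (uint64_t)seed;
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t c, mh;
    kmer_and_minhash(s, (int)s.size(), g, sd, &c, &mh);
    out[i] = (int)b->insert(c, mh) + 1;
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_bbf_may_contain(SEXP ptr, CharacterVector kmers, int g, double seed) {
  XPtr<BBF> b(ptr);
  uint64_t sd = (uint64_t)seed;
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t c, mh;
    kmer_and_minhash(s, (int)s.size(), g, sd, &c, &mh);
    out[i] = b->may_contain(c, mh);
  }
  return out;
}

// Monte-Carlo calibration: insert n_insert random k-mers, query n_query
// k-mers absent from the inserted set; reports the empirical false positive
// rate, the number of false negatives (must be 0), and per-block occupancy.
// [[Rcpp::export]]
List cpp_bbf_fpr_experiment(double n_insert, double n_query, int k, int g,
                            double bits_per_kmer, double seed, bool two_choice) {
  uint64_t sd = (uint64_t)seed;
  BBF b((double)n_insert, bits_per_kmer, sd, two_choice);
  std::mt19937_64 rng(sd ^ 0xABCDEF12ULL);
  uint64_t maskk = mask_for(k);
  std::unordered_set<uint64_t> inserted;
  std::vector<uint64_t> ins_codes;
  while ((double)inserted.size() < n_insert) {
    uint64_t fwd = rng() & maskk;
    uint64_t c = canon_code(fwd, k);
    if (inserted.insert(c).second) ins_codes.push_back(c);
  }
  for (uint64_t c : ins_codes) {
    uint64_t mh = min_interior_hash(c, k, g, sd);
    b.insert(c, mh);
  }
  // no false negatives
  double fn = 0;
  for (uint64_t c : ins_codes) {
    uint64_t mh = min_interior_hash(c, k, g, sd);
    if (!b.may_contain(c, mh)) fn += 1;
  }
  // false positives on absent k-mers
  double fp = 0, nq = 0;
  while (nq < n_query) {
    uint64_t fwd = rng() & maskk;
    uint64_t c = canon_code(fwd, k);
    if (inserted.count(c)) continue;
    uint64_t mh = min_interior_hash(c, k, g, sd);
    if (b.may_contain(c, mh)) fp += 1;
    nq += 1;
  }
  IntegerVector occ((R_xlen_t)b.occ.size());
  for (size_t i = 0; i < b.occ.size(); ++i) occ[(R_xlen_t)i] = (int)b.occ[i];
  return List::create(_["fpr"] = fp / nq, _["false_negatives"] = fn,
                      _["f"] = b.f, _["m"] = (double)(b.nb_blocks * BBF::BLOCK_BITS),
                      _["occupancy"] = occ);
}

// ---------------------------------------------------------------------------
// two-pass read filtering: BBF1 holds k-mers seen >= 1x, BBF2 those seen
// >= 2x (reads mode); in reference mode every k-mer goes straight to BBF2
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_filter_sequences(CharacterVector seqs, int k, int g,
                          double n_expected1, double n_expected2,
                          double bits_per_kmer, double seed, bool reference_mode) {
  uint64_t sd = (uint64_t)seed;
  XPtr<BBF> bbf2(new BBF(n_expected2, bits_per_kmer, splitmix64(sd ^ 2ULL)), true);
  bbf2.attr("class") = "bbf_ptr";
  BBF* bbf1 = reference_mode ? nullptr
                             : new BBF(n_expected1, bits_per_kmer, splitmix64(sd ^ 1ULL));
  double n_seq = 0, n_scanned = 0, n_promoted = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    n_seq += 1;
    for (const auto& run : acgt_runs(s)) {
      if (run.second < (size_t)k) continue;
      std::string sub = s.substr(run.first, run.second);
      std::vector<MiniOcc> mins = run_minimizers(sub, k, g, sd);
      for (size_t j = 0; j < mins.size(); ++j) {
        uint64_t fwd = encode_dna(sub, j, k);
        uint64_t c = canon_code(fwd, k);
        uint64_t mh = mins[j].hash;
        n_scanned += 1;
        if (reference_mode) {
          bbf2->insert(c, mh);
          n_promoted += 1;
        } else if (bbf1->may_contain(c, mh)) {
          bbf2->insert(c, mh);
          n_promoted += 1;
        } else {
          bbf1->insert(c, mh);
        }
      }
    }
  }
  delete bbf1; // BBF1 is discarded; the graph is built from BBF2 only
  return List::create(_["bbf2"] = bbf2,
                      _["stats"] = List::create(_["n_sequences"] = n_seq,
                                                _["n_kmers_scanned"] = n_scanned,
                                                _["n_promoted"] = n_promoted));
}
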