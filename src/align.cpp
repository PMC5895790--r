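#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base codes; anything that is not A/C/G/T maps to 4 and never matches.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

// Affine-gap local alignment (Smith-Waterman) score. A gap of length k costs
// gap_open + k * gap_extend (BLASTn -G/-E convention). N never matches.
static int sw_score_enc(const std::vector<int>& a, const std::vector<int>& b,
                        int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  const int open_cost = gap_open + gap_extend;  // cost of the first gapped base
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;        // H[i-1][j-1]
    int F = NEG;         // gap in b (vertical), recomputed along the row
    H[0] = 0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - open_cost);       // gap in a
      F = std::max(F - gap_extend, H[j - 1] - open_cost);
      int sub = (a[i - 1] == b[j - 1] && a[i - 1] < 4) ? match : mismatch;
      int h = diag + sub;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  std::vector<int> ea = encode(a), eb = encode(b);
  return sw_score_enc(ea, eb, match, mismatch, gap_open, gap_extend);
}

// [[Rcpp::export(name = ".sw_scores_cpp")]]
IntegerVector sw_scores_cpp(CharacterVector reads, std::string ref, int match,
                            int mismatch, int gap_open, int gap_extend) {
  std::vector<int> er = encode(ref);
  IntegerVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    if (r.empty()) { out[i] = 0; continue; }
    std::vector<int> ea = encode(r);
    out[i] = sw_score_enc(ea, er, match, mismatch, gap_open, gap_extend);
  }
  return out;
}

// k-mer codes of a sequence (2 bits per base); windows containing N are skipped.
static void kmer_codes(const std::vector<int>& s, int k,
                       std::vector<uint64_t>& out) {
  out.clear();
  if ((int)s.size() < k) return;
  uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // length of current N-free suffix
  for (size_t i = 0; i < s.size(); ++i) {
    if (s[i] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)s[i]) & mask;
    if (++run >= k) out.push_back(code);
  }
}

// Best-hit assignment of reads to repeat families.
// member_seqs: all reference member sequences INCLUDING their reverse
// complements; member_family: 1-based family index (families sorted
// lexicographically by name) for each member. word_size <= 0 disables seeding.
// Returns per-read best family index (0 = unassigned), score, and a tie flag.
// [[Rcpp::export(name = ".assign_reads_cpp")]]
List assign_reads_cpp(CharacterVector reads, CharacterVector member_seqs,
                      IntegerVector member_family, int n_families, int match,
                      int mismatch, int gap_open, int gap_extend, int word_size,
                      int min_score) {
  const int nm = member_seqs.size();
  std::vector<std::vector<int>> enc_members(nm);
  for (int i = 0; i < nm; ++i)
    enc_members[i] = encode(as<std::string>(member_seqs[i]));

  // per-family k-mer index over all member sequences
  std::vector<std::unordered_set<uint64_t>> index(n_families);
  std::vector<uint64_t> buf;
  if (word_size > 0) {
    for (int i = 0; i < nm; ++i) {
      kmer_codes(enc_members[i], word_size, buf);
      index[member_family[i] - 1].insert(buf.begin(), buf.end());
    }
  }

  const R_xlen_t nr = reads.size();
  IntegerVector fam(nr), score(nr);
  LogicalVector tie(nr);
  std::vector<uint64_t> rk;
  for (R_xlen_t r = 0; r < nr; ++r) {
    std::vector<int> er = encode(as<std::string>(reads[r]));
    if (word_size > 0) kmer_codes(er, word_size, rk);
    int best = 0, best_fam = 0;
    bool tied = false;
    for (int f = 0; f < n_families; ++f) {
      if (word_size > 0) {
        bool seeded = false;
        for (size_t i = 0; i < rk.size(); ++i)
          if (index[f].count(rk[i])) { seeded = true; break; }
        if (!seeded) continue;
      }
      int fs = 0;
      for (int i = 0; i < nm; ++i) {
        if (member_family[i] != f + 1) continue;
        int s = sw_score_enc(er, enc_members[i], match, mismatch, gap_open,
                             gap_extend);
        if (s > fs) fs = s;
      }
      if (fs > best) { best = fs; best_fam = f + 1; tied = false; }
      else if (fs == best && fs > 0 && best_fam != 0 && best_fam != f + 1)
        tied = true;
    }
    if (best >= min_score && best_fam != 0) {
      fam[r] = best_fam;
      score[r] = best;
      tie[r] = tied;
    } else {
      // unassigned: report 0, not the sub-threshold best, so that results
      // are identical with and without seed-filter acceleration
      fam[r] = 0;
      score[r] = 0;
      tie[r] = false;
    }
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["family"] = fam, _["score"] = score, _["tie"] = tie);
}
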