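// Hot loops of the read simulator and genotyper. All randomness goes
// through R's RNG so that set.seed() on the R side makes every stage
// reproducible.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

// Substitution errors: per read, draw the error count Binomial(len, rate),
// then flip that many distinct positions to a different base.
static void apply_errors(std::string& read, double rate) {
  if (rate <= 0.0) return;
  int n = (int)R::rbinom((double)read.size(), rate);
  for (int e = 0; e < n; ++e) {
    int pos = (int)(unif_rand() * read.size());
    if (pos >= (int)read.size()) pos = read.size() - 1;
    char old = read[pos];
    char nb = old;
    while (nb == old) nb = BASES[(int)(unif_rand() * 4) & 3];
    read[pos] = nb;
  }
}

// Build paired-end reads from fragment templates. templates[tmpl_idx[i]-1]
// is the i-th fragment's full product sequence; R1 is its first read_len
// bases, R2 the reverse complement of its last read_len bases (read-through
// is trimmed to the product for short templates). With
// randomize_orientation, R1/R2 are swapped with probability 1/2,
// emulating random fragment orientation on the flow cell.
// [[Rcpp::export]]
List cpp_make_reads(CharacterVector templates, IntegerVector tmpl_idx,
                    int read_len, double error_rate,
                    bool randomize_orientation) {
  int n = tmpl_idx.size();
  std::vector<std::string> tmpl(templates.size());
  for (int i = 0; i < templates.size(); ++i)
    tmpl[i] = as<std::string>(templates[i]);
  CharacterVector r1(n), r2(n);
  for (int i = 0; i < n; ++i) {
    const std::string& t = tmpl[tmpl_idx[i] - 1];
    int L = t.size();
    int rl = std::min(read_len, L);
    std::string a = t.substr(0, rl);
    std::string b = revcomp_str(t.substr(L - rl, rl));
    apply_errors(a, error_rate);
    apply_errors(b, error_rate);
    bool swap = randomize_orientation && unif_rand() < 0.5;
    r1[i] = swap ? b : a;
    r2[i] = swap ? a : b;
  }
  return List::create(_["r1"] = r1, _["r2"] = r2);
}

// --- primer-anchored read assignment -------------------------------------
//
// Primers all share one length P. A read "begins with" a primer if its
// first P bases match with at most one mismatch. Candidate primers are
// found by exact lookup of either half of the prefix (pigeonhole: one
// mismatch leaves at least one half intact), then verified.

struct PrimerIndex {
  int plen, half;
  std::vector<std::string> primers;   // 2*A entries: fwd then rev per amp
  std::vector<int> amp;               // amplicon index (1-based)
  std::vector<int> is_fwd;            // 1 if forward primer
  std::unordered_multimap<std::string, int> h1, h2;
};

static void build_index(PrimerIndex& ix, CharacterVector fwd,
                        CharacterVector rev) {
  int A = fwd.size();
  ix.plen = LENGTH(STRING_ELT(fwd, 0));
  ix.half = ix.plen / 2;
  for (int a = 0; a < A; ++a) {
    std::string f = as<std::string>(fwd[a]);
    std::string r = as<std::string>(rev[a]);
    if ((int)f.size() != ix.plen || (int)r.size() != ix.plen)
      stop("all primers must share one length");
    ix.primers.push_back(f); ix.amp.push_back(a + 1); ix.is_fwd.push_back(1);
    ix.primers.push_back(r); ix.amp.push_back(a + 1); ix.is_fwd.push_back(0);
  }
  for (size_t k = 0; k < ix.primers.size(); ++k) {
    ix.h1.insert({ix.primers[k].substr(0, ix.half), (int)k});
    ix.h2.insert({ix.primers[k].substr(ix.half, ix.plen - ix.half), (int)k});
  }
}

static inline int hamming_le1(const char* a, const char* b, int n) {
  int mm = 0;
  for (int i = 0; i < n; ++i)
    if (a[i] != b[i] && ++mm > 1) return 2;
  return mm;
}

// Collect primer matches for one read prefix into (amplicon, is_fwd) hits.
static void match_read(const PrimerIndex& ix, const char* seq, int len,
                       std::vector<std::pair<int,int> >& hits) {
  if (len < ix.plen) return;
  std::string p1(seq, ix.half), p2(seq + ix.half, ix.plen - ix.half);
  std::vector<int> cand;
  auto r1 = ix.h1.equal_range(p1);
  for (auto it = r1.first; it != r1.second; ++it) cand.push_back(it->second);
  auto r2 = ix.h2.equal_range(p2);
  for (auto it = r2.first; it != r2.second; ++it) cand.push_back(it->second);
  for (int k : cand) {
    if (hamming_le1(seq, ix.primers[k].c_str(), ix.plen) <= 1) {
      std::pair<int,int> hit(ix.amp[k], ix.is_fwd[k]);
      bool seen = false;
      for (auto& h : hits) if (h == hit) { seen = true; break; }
      if (!seen) hits.push_back(hit);
    }
  }
}

// Assign read pairs to amplicons. Returns, per pair:
//   amplicon: 1-based amplicon index, 0 = OFF_TARGET, -1 = AMBIGUOUS
//   fwd_read: 1 if r1 carries the forward primer (covers product start),
//             2 if r2 does, 0 if undetermined.
// [[Rcpp::export]]
List cpp_assign_reads(CharacterVector r1, CharacterVector r2,
                      CharacterVector fwd, CharacterVector rev) {
  PrimerIndex ix;
  build_index(ix, fwd, rev);
  int n = r1.size();
  IntegerVector amp_out(n), fwd_read(n);
  std::vector<std::pair<int,int> > hits1, hits2;
  for (int i = 0; i < n; ++i) {
    hits1.clear(); hits2.clear();
    const char* s1 = CHAR(STRING_ELT(r1, i));
    const char* s2 = CHAR(STRING_ELT(r2, i));
    match_read(ix, s1, LENGTH(STRING_ELT(r1, i)), hits1);
    match_read(ix, s2, LENGTH(STRING_ELT(r2, i)), hits2);
    std::vector<int> amps;
    for (auto& h : hits1) if (std::find(amps.begin(), amps.end(), h.first) == amps.end()) amps.push_back(h.first);
    for (auto& h : hits2) if (std::find(amps.begin(), amps.end(), h.first) == amps.end()) amps.push_back(h.first);
    if (amps.size() == 0) { amp_out[i] = 0; fwd_read[i] = 0; }
    else if (amps.size() > 1) { amp_out[i] = -1; fwd_read[i] = 0; }
    else {
      amp_out[i] = amps[0];
      int fr = 0;
      for (auto& h : hits1) if (h.first == amps[0] && h.second == 1) fr = 1;
      if (fr == 0)
        for (auto& h : hits2) if (h.first == amps[0] && h.second == 1) fr = 2;
      // a read matching the reverse primer implies its mate is the
      // forward-strand read
      if (fr == 0) {
        for (auto& h : hits1) if (h.first == amps[0] && h.second == 0) fr = 2;
        if (fr == 0) fr = 1;
      }
      fwd_read[i] = fr;
    }
  }
  return List::create(_["amplicon"] = amp_out, _["fwd_read"] = fwd_read);
}

static bool contains(const char* s, int slen, const std::string& pat) {
  int m = pat.size();
  if (m == 0 || m > slen) return false;
  const char* p = pat.c_str();
  for (int i = 0; i + m <= slen; ++i) {
    if (memcmp(s + i, p, m) == 0) return true;
  }
  return false;
}

// Haplotype-context voting. patterns = c(ref_ctx, alt_ctx_1, ...). For each
// read with spans[i] true, count an exact containment (either strand) of
// exactly one pattern as that pattern's vote; multiple or zero pattern
// matches count as "other". Returns votes of length(patterns) + 1 with the
// last element = other.
// [[Rcpp::export]]
IntegerVector cpp_vote_counts(CharacterVector reads, LogicalVector spans,
                              CharacterVector patterns) {
  int np = patterns.size();
  std::vector<std::string> pat(np), patrc(np);
  for (int j = 0; j < np; ++j) {
    pat[j] = as<std::string>(patterns[j]);
    patrc[j] = revcomp_str(pat[j]);
  }
  IntegerVector votes(np + 1);
  for (int i = 0; i < reads.size(); ++i) {
    if (!spans[i]) continue;
    const char* s = CHAR(STRING_ELT(reads, i));
    int slen = LENGTH(STRING_ELT(reads, i));
    int hit = -1; int nhit = 0;
    for (int j = 0; j < np; ++j) {
      if (contains(s, slen, pat[j]) || contains(s, slen, patrc[j])) {
        hit = j; ++nhit;
      }
    }
    if (nhit == 1) votes[hit]++;
    else votes[np]++;
  }
  return votes;
}

// Number of reads containing the pattern (either strand) as an exact
// substring; used for junction-support counting.
// [[Rcpp::export]]
int cpp_count_support(CharacterVector reads, std::string pattern) {
  std::string rc = revcomp_str(pattern);
  int n = 0;
  for (int i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int slen = LENGTH(STRING_ELT(reads, i));
    if (contains(s, slen, pattern) || contains(s, slen, rc)) ++n;
  }
  return n;
}
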