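// Mismatch-tolerant protospacer search against a normal genome.
//
// A GenomeIdx holds the concatenated genome (contigs separated by runs of N,
// which can never sit inside a valid frame) plus an exact k-mer position
// index. Queries use the pigeonhole principle: a 20-mer hit with <= m
// mismatches must contain at least one exact chunk when the query is split
// into m+1 disjoint k-length chunks, so chunk lookups enumerate a candidate
// superset that is then verified by direct Hamming comparison. When
// (m+1)*k > 20 the pigeonhole argument no longer applies and the search
// falls back to a full scan; both paths verify identically.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int code_base(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1; // N and anything else: never matches
  }
}

struct GenomeIdx {
  std::string seq;                      // concatenated, uppercase
  std::vector<int8_t> code;             // -1 for N / spacer
  int k;
  std::vector<std::string> names;
  std::vector<int> starts;              // global 0-based start per contig
  std::vector<int> lens;
  std::vector<std::vector<int>> buckets; // 4^k buckets of global positions
  std::vector<int> stamp;                // scratch for candidate dedup
  int stamp_id = 0;
};

static const int SPACER = 30;

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, CharacterVector names, int k) {
  if (k < 3 || k > 12) stop("index k must be in [3, 12]");
  GenomeIdx* g = new GenomeIdx();
  g->k = k;
  size_t total = 0;
  for (int i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i)) + SPACER;
  g->seq.reserve(total);
  for (int i = 0; i < seqs.size(); ++i) {
    g->names.push_back(as<std::string>(names[i]));
    g->starts.push_back((int)g->seq.size());
    std::string s = as<std::string>(seqs[i]);
    g->lens.push_back((int)s.size());
    g->seq += s;
    g->seq.append(SPACER, 'N');
  }
  const int L = (int)g->seq.size();
  g->code.resize(L);
  for (int i = 0; i < L; ++i) g->code[i] = (int8_t)code_base(g->seq[i]);

  g->buckets.assign((size_t)1 << (2 * k), std::vector<int>());
  const uint32_t mask = ((uint32_t)1 << (2 * k)) - 1;
  uint32_t key = 0;
  int run = 0; // number of consecutive valid bases ending at i
  for (int i = 0; i < L; ++i) {
    int c = g->code[i];
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint32_t)c) & mask;
    if (++run >= k) g->buckets[key].push_back(i - k + 1);
  }
  XPtr<GenomeIdx> ptr(g, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP idx) {
  XPtr<GenomeIdx> g(idx);
  return List::create(_["k"] = g->k,
                      _["contigs"] = wrap(g->names),
                      _["lengths"] = wrap(g->lens));
}

static inline int hamming_leq(const int8_t* gc, const int* pat, int max_mm) {
  // returns mismatch count, or max_mm+1 as soon as the budget is exceeded;
  // any invalid (N) genome base disqualifies the frame (returns max_mm+21)
  int mm = 0;
  for (int j = 0; j < 20; ++j) {
    int c = gc[j];
    if (c < 0) return max_mm + 21;
    if (c != pat[j]) { if (++mm > max_mm) return mm; }
  }
  return mm;
}

struct HitSink {
  std::vector<int> query, start, mism;
  std::vector<std::string> contig, strand, pam, pam_class;
};

// classify the PAM for a '+' frame whose protospacer starts at global s
static inline int pam_plus(const GenomeIdx& g, int s, bool ngg, bool nag) {
  if (s + 23 > (int)g.seq.size()) return 0;
  int n0 = g.code[s + 20], p2 = g.code[s + 21], p3 = g.code[s + 22];
  if (n0 < 0 || p2 < 0 || p3 < 0) return 0;
  if (ngg && p2 == 2 && p3 == 2) return 1; // NGG
  if (nag && p2 == 0 && p3 == 2) return 2; // NAG
  return 0;
}

// classify the PAM for a '-' frame: plus-strand layout is [pam'][protospacer']
// with the protospacer-matched 20-mer starting at global s
static inline int pam_minus(const GenomeIdx& g, int s, bool ngg, bool nag) {
  if (s < 3) return 0;
  int c1 = g.code[s - 3], c2 = g.code[s - 2], n0 = g.code[s - 1];
  if (c1 < 0 || c2 < 0 || n0 < 0) return 0;
  if (ngg && c1 == 1 && c2 == 1) return 1; // revcomp(NGG) = CCN
  if (nag && c1 == 1 && c2 == 3) return 2; // revcomp(NAG) = CTN
  return 0;
}

static void gather_candidates(GenomeIdx& g, const int* pat, int max_mm,
                              std::vector<int>& cand) {
  cand.clear();
  const int k = g.k;
  const int nchunk = max_mm + 1;
  if (g.stamp.size() != g.seq.size()) g.stamp.assign(g.seq.size(), -1);
  const int id = ++g.stamp_id;
  for (int j = 0; j < nchunk; ++j) {
    int off = j * k;
    uint32_t key = 0;
    for (int t = 0; t < k; ++t) key = (key << 2) | (uint32_t)pat[off + t];
    const std::vector<int>& b = g.buckets[key];
    for (size_t t = 0; t < b.size(); ++t) {
      int s = b[t] - off;
      if (s >= 0 && g.stamp[s] != id) { g.stamp[s] = id; cand.push_back(s); }
    }
  }
}

static void emit(const GenomeIdx& g, HitSink& out, int qi, int s, bool plus,
                 int mm, int pclass) {
  // map global position to contig (starts are sorted)
  int lo = 0, hi = (int)g.starts.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (g.starts[mid] <= s) lo = mid; else hi = mid - 1;
  }
  out.query.push_back(qi + 1);
  out.contig.push_back(g.names[lo]);
  out.start.push_back(s - g.starts[lo]);
  out.strand.push_back(plus ? "+" : "-");
  out.mism.push_back(mm);
  std::string pam;
  if (plus) {
    pam = g.seq.substr(s + 20, 3);
  } else {
    std::string raw = g.seq.substr(s - 3, 3);
    pam.resize(3);
    for (int j = 0; j < 3; ++j) {
      char c = raw[2 - j];
      pam[j] = (c == 'A') ? 'T' : (c == 'C') ? 'G' : (c == 'G') ? 'C'
             : (c == 'T') ? 'A' : 'N';
    }
  }
  out.pam.push_back(pam);
  out.pam_class.push_back(pclass == 1 ? "NGG" : "NAG");
}

// [[Rcpp::export]]
DataFrame cpp_find_hits(SEXP idx, CharacterVector protospacers, int max_mm,
                        bool allow_ngg, bool allow_nag) {
  XPtr<GenomeIdx> gp(idx);
  GenomeIdx& g = *gp;
  if (max_mm < 0 || max_mm > 6) stop("max_mm must be in [0, 6]");
  const int L = (int)g.seq.size();
  HitSink out;
  std::vector<int> cand;
  const bool use_index = (max_mm + 1) * g.k <= 20;

  for (int qi = 0; qi < protospacers.size(); ++qi) {
    std::string p = as<std::string>(protospacers[qi]);
    if ((int)p.size() != 20) stop("protospacer must be 20 nt");
    int fwd[20], rev[20];
    for (int j = 0; j < 20; ++j) {
      int c = code_base(p[j]);
      if (c < 0) stop("protospacer must be over ACGT");
      fwd[j] = c;
      rev[19 - j] = 3 - c; // reverse complement
    }
    for (int pass = 0; pass < 2; ++pass) {
      const int* pat = (pass == 0) ? fwd : rev;
      const bool plus = (pass == 0);
      if (use_index) {
        gather_candidates(g, pat, max_mm, cand);
        for (size_t t = 0; t < cand.size(); ++t) {
          int s = cand[t];
          if (s + 20 > L) continue;
          int pclass = plus ? pam_plus(g, s, allow_ngg, allow_nag)
                            : pam_minus(g, s, allow_ngg, allow_nag);
          if (!pclass) continue;
          int mm = hamming_leq(&g.code[s], pat, max_mm);
          if (mm <= max_mm) emit(g, out, qi, s, plus, mm, pclass);
        }
      } else {
        for (int s = 0; s + 20 <= L; ++s) {
          int pclass = plus ? pam_plus(g, s, allow_ngg, allow_nag)
                            : pam_minus(g, s, allow_ngg, allow_nag);
          if (!pclass) continue;
          int mm = hamming_leq(&g.code[s], pat, max_mm);
          if (mm <= max_mm) emit(g, out, qi, s, plus, mm, pclass);
        }
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(out.query),
                           _["contig"] = wrap(out.contig),
                           _["start"] = wrap(out.start),
                           _["strand"] = wrap(out.strand),
                           _["mismatches"] = wrap(out.mism),
                           _["pam"] = wrap(out.pam),
                           _["pam_class"] = wrap(out.pam_class),
                           _["stringsAsFactors"] = false);
}
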