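#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Base codes: A=0 C=1 G=2 T=3; anything else (incl. N) = 4 and never matches.
static std::vector<uint8_t> encode_seq(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    switch (s[k]) {
      case 'A': case 'a': v[k] = 0; break;
      case 'C': case 'c': v[k] = 1; break;
      case 'G': case 'g': v[k] = 2; break;
      case 'T': case 't': v[k] = 3; break;
      default: v[k] = 4;
    }
  }
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  size_t n = v.size();
  std::vector<uint8_t> r(n);
  for (size_t k = 0; k < n; ++k) {
    uint8_t b = v[n - 1 - k];
    r[k] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

struct Aln { int score, matches, columns; };

// Ordering among co-optimal cells: score desc, then matches desc, then
// fewer columns (keeps the reported overlap minimal and deterministic).
static inline bool better(int s1, int m1, int c1, int s2, int m2, int c2) {
  if (s1 != s2) return s1 > s2;
  if (m1 != m2) return m1 > m2;
  return c1 < c2;
}

// Overlap (free end-gap) alignment by full dynamic programming.
// Leading/trailing gaps in either sequence are free; internal gaps and
// mismatches are penalised through `gap` / `mismatch`. Alongside the score
// we carry the number of match columns and total aligned columns of the
// optimal path so identity = matches / columns can be reported exactly.
//
// For speed each DP cell packs (score desc, matches desc, columns asc) into
// one int64 so the lexicographic maximum is a plain integer max:
//   bits 34..52  score + SOFF   (score bounded by +-2 * total length)
//   bits 17..33  matches
//   bits  0..16  CMAX - columns (so fewer columns compares greater)
// Field widths hold for sequences up to ~30 kb, far beyond read lengths.
static const int64_t SOFF = 1LL << 17;
static const int64_t CMAX = (1LL << 17) - 1;

static inline int64_t pack0() { return (SOFF << 34) | CMAX; }

static Aln overlap_dp(const std::vector<uint8_t>& a, const std::vector<uint8_t>& b,
                      int match, int mismatch, int gap) {
  const int m = (int)a.size(), n = (int)b.size();
  const int64_t d_match = ((int64_t)match << 34) + (1LL << 17) - 1;
  const int64_t d_mismatch = ((int64_t)mismatch << 34) - 1;
  const int64_t d_gap = ((int64_t)gap << 34) - 1;
  std::vector<int64_t> row(n + 1, pack0());
  int64_t best = INT64_MIN;
  int64_t* E = row.data();
  for (int i = 1; i <= m; ++i) {
    const uint8_t ai = a[i - 1];
    int64_t diag = E[0];          // E[i-1][0]
    E[0] = pack0();               // free leading gap in b
    for (int j = 1; j <= n; ++j) {
      const int64_t up = E[j];    // E[i-1][j]
      int64_t v = diag + ((ai == b[j - 1] && ai < 4) ? d_match : d_mismatch);
      const int64_t ug = up + d_gap;
      if (ug > v) v = ug;
      const int64_t lg = E[j - 1] + d_gap;
      if (lg > v) v = lg;
      diag = up;
      E[j] = v;
    }
    if (E[n] > best) best = E[n]; // cell (i, n): trailing gap in b free
  }
  for (int j = 1; j <= n; ++j)    // final row: trailing gap in a free
    if (E[j] > best) best = E[j];
  const int cols = (int)(CMAX - (best & CMAX));
  if (cols < 1) return {0, 0, 0};
  const int matches = (int)((best >> 17) & CMAX);
  const int score = (int)((best >> 34) - SOFF);
  return {score, matches, cols};
}

// [[Rcpp::export(name = ".overlap_align_cpp")]]
List overlap_align_cpp(std::string a, std::string b,
                       int match = 1, int mismatch = -1, int gap = -2) {
  std::vector<uint8_t> ea = encode_seq(a), eb = encode_seq(b);
  if (ea.empty() || eb.empty()) stop("empty sequence");
  if (ea.size() + eb.size() > 30000) stop("sequences too long for overlap DP");
  Aln f = overlap_dp(ea, eb, match, mismatch, gap);
  std::vector<uint8_t> rb = revcomp(eb);
  Aln r = overlap_dp(ea, rb, match, mismatch, gap);
  return List::create(
    _["fwd"] = NumericVector::create(_["score"] = f.score, _["matches"] = f.matches,
                                     _["columns"] = f.columns),
    _["rev"] = NumericVector::create(_["score"] = r.score, _["matches"] = r.matches,
                                     _["columns"] = r.columns));
}

// Sorted unique k-mer codes of a sequence (2 bits/base); windows containing
// a non-ACGT base are skipped, so an N can never seed a pair.
static std::vector<uint32_t> kmer_set(const std::vector<uint8_t>& s, int k) {
  std::vector<uint32_t> out;
  const int n = (int)s.size();
  if (n < k) return out;
  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  uint32_t code = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    if (s[i] > 3) { run = 0; code = 0; continue; }
    code = ((code << 2) | s[i]) & mask;
    if (++run >= k) out.push_back(code);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return out;
}

static bool share_kmer(const std::vector<uint32_t>& x, const std::vector<uint32_t>& y) {
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) return true;
    if (x[i] < y[j]) ++i; else ++j;
  }
  return false;
}

// All-pairs accepted overlap hits. For every unordered pair the optimal
// overlap alignment is computed in both orientations; a pair is a hit if at
// least one orientation satisfies both thresholds, and the better-scoring
// passing orientation is reported. `kmer` > 0 enables the shared-k-mer
// prefilter (the caller guarantees losslessness for the thresholds in use).
// [[Rcpp::export(name = ".overlap_hits_cpp")]]
DataFrame overlap_hits_cpp(CharacterVector seqs, double min_overlap_frac,
                           double min_identity, int kmer = 0,
                           int match = 1, int mismatch = -1, int gap = -2) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t> > enc(n), rc(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode_seq(as<std::string>(seqs[i]));
    if (enc[i].empty()) stop("empty sequence at index %d", i + 1);
    if (enc[i].size() > 15000) stop("sequence too long for overlap DP");
    rc[i] = revcomp(enc[i]);
    len[i] = (int)enc[i].size();
  }
  std::vector<std::vector<uint32_t> > kf, kr;
  if (kmer > 0) {
    kf.resize(n); kr.resize(n);
    for (int i = 0; i < n; ++i) {
      kf[i] = kmer_set(enc[i], kmer);
      kr[i] = kmer_set(rc[i], kmer);
    }
  }
  std::vector<int> oi, oj, oorient, ocols, omatch;
  std::vector<double> oid;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (kmer > 0 && !share_kmer(kf[i], kf[j]) && !share_kmer(kf[i], kr[j])) continue;
      const double minlen = (double)std::min(len[i], len[j]);
      const double need_cols = min_overlap_frac * minlen - 1e-9;
      Aln f = overlap_dp(enc[i], enc[j], match, mismatch, gap);
      Aln r = overlap_dp(enc[i], rc[j], match, mismatch, gap);
      const bool okf = f.columns >= need_cols && f.columns >= 1 &&
        (double)f.matches >= min_identity * f.columns - 1e-9;
      const bool okr = r.columns >= need_cols && r.columns >= 1 &&
        (double)r.matches >= min_identity * r.columns - 1e-9;
      if (!okf && !okr) continue;
      Aln b; int orient;
      if (okf && okr) {
        if (better(r.score, r.matches, r.columns, f.score, f.matches, f.columns)) {
          b = r; orient = 1;
        } else { b = f; orient = 0; }
      } else if (okf) { b = f; orient = 0; } else { b = r; orient = 1; }
      oi.push_back(i + 1); oj.push_back(j + 1); oorient.push_back(orient);
      ocols.push_back(b.columns); omatch.push_back(b.matches);
      oid.push_back((double)b.matches / (double)b.columns);
    }
  }
  return DataFrame::create(
    _["i"] = oi, _["j"] = oj, _["identity"] = oid,
    _["overlap_length"] = ocols, _["matches"] = omatch,
    _["orientation"] = oorient, _["stringsAsFactors"] = false);
}
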