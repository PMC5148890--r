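#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Fixed local-alignment scoring used throughout the package:
// match +2, mismatch -3, gap open -5, gap extend -2 (a gap of length L
// costs 5 + 2L).  'N' never matches anything, including another 'N'.
static const int MATCH = 2;
static const int MISMATCH = -3;
static const int GAP_OPEN = 5;   // positive costs, subtracted
static const int GAP_EXT = 2;
static const int NEG = INT32_MIN / 4;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static inline int subst(char a, char b) {
  return (a == b && is_acgt(a)) ? MATCH : MISMATCH;
}

// Smith-Waterman with affine gaps (Gotoh), byte traceback over rolling
// score rows.  Returns score, match count, alignment columns, and the
// 0-based half-open spans of the alignment on each sequence.
// Deterministic tie-breaks: the best cell is the first (row-major) cell
// achieving the maximum score; the cell move prefers diagonal, then a
// gap in `a`, then a gap in `b`; gap-open beats gap-extend on ties.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(const std::string& a, const std::string& b) {
  const int n = (int) a.size(), m = (int) b.size();
  // per-cell traceback codes, row-major (n+1) x (m+1):
  // TH: 0 stop, 1 diag, 2 left (gap in a), 3 up (gap in b)
  std::vector<uint8_t> TH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> TE((size_t)(n + 1) * (m + 1), 0); // 1 = opened here
  std::vector<uint8_t> TF((size_t)(n + 1) * (m + 1), 0);

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    uint8_t* THr = &TH[(size_t) i * (m + 1)];
    uint8_t* TEr = &TE[(size_t) i * (m + 1)];
    uint8_t* TFr = &TF[(size_t) i * (m + 1)];
    int e = NEG;
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int e_open = Hcur[j - 1] - GAP_OPEN - GAP_EXT;
      int e_ext = e - GAP_EXT;
      if (e_open >= e_ext) { e = e_open; TEr[j] = 1; }
      else { e = e_ext; TEr[j] = 0; }

      int f_open = Hprev[j] - GAP_OPEN - GAP_EXT;
      int f_ext = Fcol[j] - GAP_EXT;
      if (f_open >= f_ext) { Fcol[j] = f_open; TFr[j] = 1; }
      else { Fcol[j] = f_ext; TFr[j] = 0; }

      int diag = Hprev[j - 1] + subst(ai, b[j - 1]);
      int h = 0; uint8_t t = 0;
      if (diag >= h) { h = diag; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      Hcur[j] = h; THr[j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }

  int matches = 0, columns = 0;
  int i = bi, j = bj;
  if (best > 0) {
    auto idx = [m](int i_, int j_) { return (size_t) i_ * (m + 1) + j_; };
    int state = 0;   // 0 in H, 2 in E (gap run in a), 3 in F (gap in b)
    while (true) {
      if (state == 0) {
        uint8_t t = TH[idx(i, j)];
        if (t == 0) break;
        if (t == 1) {
          ++columns;
          if (subst(a[i - 1], b[j - 1]) == MATCH) ++matches;
          --i; --j;
        } else if (t == 2) {
          state = 2;
        } else {
          state = 3;
        }
      } else if (state == 2) {
        ++columns;
        uint8_t open = TE[idx(i, j)];
        --j;
        if (open) state = 0;
      } else {
        ++columns;
        uint8_t open = TF[idx(i, j)];
        --i;
        if (open) state = 0;
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["matches"] = matches,
    _["columns"] = columns,
    _["a_start"] = i,      // 0-based start on a
    _["a_end"] = bi,       // half-open end on a
    _["b_start"] = j,
    _["b_end"] = bj);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'T': c = 'A'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

static void collect_kmers(const std::string& s, int k,
                          std::unordered_set<uint64_t>& out) {
  const int n = (int) s.size();
  uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: v = -1;
    }
    if (v < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) v) & mask;
    if (++run >= k) out.insert(code);
  }
}

// TRUE when a and b share at least one exact k-mer over {A,C,G,T}.
// [[Rcpp::export(name = ".kmer_share_cpp")]]
bool kmer_share_cpp(const std::string& a, const std::string& b, int k) {
  if (k < 1 || (int) a.size() < k || (int) b.size() < k) return false;
  const std::string& small = (a.size() <= b.size()) ? a : b;
  const std::string& large = (a.size() <= b.size()) ? b : a;
  std::unordered_set<uint64_t> set;
  collect_kmers(small, k, set);
  if (set.empty()) return false;
  const int n = (int) large.size();
  uint64_t code = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int v;
    switch (large[i]) {
      case 'A': v = 0; break; case 'C': v = 1; break;
      case 'G': v = 2; break; case 'T': v = 3; break;
      default: v = -1;
    }
    if (v < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t) v) & mask;
    if (++run >= k && set.count(code)) return true;
  }
  return false;
}
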