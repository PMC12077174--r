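#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise DP over IUPAC nucleotide codes, banded around the main
// diagonal. Two modes: "overlap" (semi-global, end gaps on either sequence
// free) and "global" (end gaps penalized). A gap of length L costs
// gap_open + L * gap_extend.

static const int NEG = -1000000000;

static inline int base_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'M': return 3;  case 'R': return 5;  case 'W': return 9;  case 'S': return 6;
    case 'Y': return 10; case 'K': return 12; case 'V': return 7;  case 'H': return 11;
    case 'D': return 13; case 'B': return 14; case 'N': return 15;
    default: return -1;
  }
}

struct Band {
  int lo, hi, w;
  inline bool in(int i, int j) const { int d = j - i; return d >= lo && d <= hi; }
  inline size_t idx(int i, int j) const {
    return (size_t)i * (size_t)w + (size_t)(j - i - lo);
  }
};

// [[Rcpp::export]]
List align_dp_cpp(std::string q, std::string t,
                  int match, int mismatch, int gap_open, int gap_extend,
                  int band, bool global_mode) {
  const int n = (int)q.size(), m = (int)t.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> qm(n), tm(m);
  for (int i = 0; i < n; ++i) {
    qm[i] = base_mask(q[i]);
    if (qm[i] < 0)
      stop("invalid nucleotide character in query: '" + std::string(1, q[i]) + "'");
  }
  for (int j = 0; j < m; ++j) {
    tm[j] = base_mask(t[j]);
    if (tm[j] < 0)
      stop("invalid nucleotide character in target: '" + std::string(1, t[j]) + "'");
  }

  Band B;
  if (band <= 0) { B.lo = -n; B.hi = m; }
  else {
    B.lo = std::min(0, m - n) - band;
    B.hi = std::max(0, m - n) + band;
    if (B.lo < -n) B.lo = -n;
    if (B.hi > m)  B.hi = m;
  }
  B.w = B.hi - B.lo + 1;

  const size_t sz = (size_t)(n + 1) * (size_t)B.w;
  std::vector<int> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // X = column with query char over target gap; Y = gap in query over target char
  auto gv = [&](const std::vector<int>& A, int i, int j) -> int {
    if (i < 0 || j < 0 || i > n || j > m || !B.in(i, j)) return NEG;
    return A[B.idx(i, j)];
  };

  if (global_mode) {
    if (B.in(0, 0)) M[B.idx(0, 0)] = 0;
    for (int j = 1; j <= m; ++j)
      if (B.in(0, j)) Y[B.idx(0, j)] = -gap_open - j * gap_extend;
    for (int i = 1; i <= n; ++i)
      if (B.in(i, 0)) X[B.idx(i, 0)] = -gap_open - i * gap_extend;
  } else {
    for (int j = 0; j <= m; ++j) if (B.in(0, j)) M[B.idx(0, j)] = 0;
    for (int i = 0; i <= n; ++i) if (B.in(i, 0)) M[B.idx(i, 0)] = 0;
  }

  for (int i = 1; i <= n; ++i) {
    const int jlo = std::max(1, i + B.lo), jhi = std::min(m, i + B.hi);
    for (int j = jlo; j <= jhi; ++j) {
      const size_t id = B.idx(i, j);
      int a = gv(M, i - 1, j), b = gv(X, i - 1, j);
      X[id] = std::max(a == NEG ? NEG : a - gap_open - gap_extend,
                       b == NEG ? NEG : b - gap_extend);
      int c = gv(M, i, j - 1), d = gv(Y, i, j - 1);
      Y[id] = std::max(c == NEG ? NEG : c - gap_open - gap_extend,
                       d == NEG ? NEG : d - gap_extend);
      int diag = std::max(gv(M, i - 1, j - 1),
                          std::max(gv(X, i - 1, j - 1), gv(Y, i - 1, j - 1)));
      M[id] = (diag == NEG) ? NEG
                            : diag + ((qm[i - 1] & tm[j - 1]) ? match : mismatch);
    }
  }

  int bi = 0, bj = 0, bs = NEG;
  char bstate = 'M';
  if (global_mode) {
    bi = n; bj = m;
    const int vm = gv(M, n, m), vx = gv(X, n, m), vy = gv(Y, n, m);
    bs = std::max(vm, std::max(vx, vy));
    if (bs == NEG) stop("band does not reach the terminal cell; widen the band");
    bstate = (bs == vm) ? 'M' : ((bs == vx) ? 'X' : 'Y');
  } else {
    for (int j = 0; j <= m; ++j) {
      const int v = gv(M, n, j);
      if (v > bs) { bs = v; bi = n; bj = j; }
    }
    for (int i = 0; i <= n; ++i) {
      const int v = gv(M, i, m);
      if (v > bs) { bs = v; bi = i; bj = m; }
    }
    if (bs == NEG) stop("band does not reach any terminal cell; widen the band");
  }

  std::string aq, at;
  aq.reserve(n + m); at.reserve(n + m);
  int i = bi, j = bj;
  char st = bstate;
  while (true) {
    if (global_mode) { if (i == 0 && j == 0) break; }
    else { if (i == 0 || j == 0) break; }
    if (st == 'M') {
      aq.push_back(q[i - 1]); at.push_back(t[j - 1]);
      const int v = M[B.idx(i, j)];
      const int sc = (qm[i - 1] & tm[j - 1]) ? match : mismatch;
      const int pm = gv(M, i - 1, j - 1), px = gv(X, i - 1, j - 1);
      if (pm != NEG && v == pm + sc) st = 'M';
      else if (px != NEG && v == px + sc) st = 'X';
      else st = 'Y';
      --i; --j;
    } else if (st == 'X') {
      aq.push_back(q[i - 1]); at.push_back('-');
      const int v = X[B.idx(i, j)];
      const int pm = gv(M, i - 1, j);
      st = (pm != NEG && v == pm - gap_open - gap_extend) ? 'M' : 'X';
      --i;
    } else {
      aq.push_back('-'); at.push_back(t[j - 1]);
      const int v = Y[B.idx(i, j)];
      const int pm = gv(M, i, j - 1);
      st = (pm != NEG && v == pm - gap_open - gap_extend) ? 'M' : 'Y';
      --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(at.begin(), at.end());

  return List::create(
    _["score"] = bs,
    _["aligned_query"] = aq,
    _["aligned_target"] = at,
    _["query_start"] = i + 1, _["query_end"] = bi,
    _["target_start"] = j + 1, _["target_end"] = bj);
}

// Tally aligned read columns into a per-profile-column base/gap count matrix.
// counts is a 5 x ncol integer matrix (rows A,C,G,T,gap) modified in place.
// col_map maps positions of the alignment target string (profile majority
// string) to profile column indices (1-based).
// [[Rcpp::export]]
void tally_alignment_cpp(IntegerMatrix counts, std::string aq, std::string at,
                         int target_start, IntegerVector col_map) {
  int tp = target_start - 1; // 0-based index of next target char
  const size_t L = aq.size();
  for (size_t k = 0; k < L; ++k) {
    const char tc = at[k];
    if (tc == '-') continue; // read insertion relative to profile: dropped
    const int col = col_map[tp] - 1;
    ++tp;
    if (col < 0) continue;   // profile column with gap-majority: no slot
    int row;
    switch (aq[k]) {
      case 'A': row = 0; break; case 'C': row = 1; break;
      case 'G': row = 2; break; case 'T': row = 3; break;
      case '-': row = 4; break;
      default: continue;     // N / ambiguity in a read casts no vote
    }
    ++counts(row, col);
  }
}
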