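#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// 2-bit nucleotide codes: A=0, C=1, G=2, T=3.  The sentinel terminating the
// concatenated reference is implicit: a comparison that runs past the end of
// the text treats the text side as smaller than any base.

// Compare the suffix starting at `pos` against query `q` (prefix semantics).
// Returns -1 if suffix < q, 0 if q is a prefix of the suffix, +1 if suffix > q.
// When `lcp` is non-null it receives the matched prefix length.
static inline int suf_cmp_q(const uint8_t* g, int n, long long pos,
                            const uint8_t* q, int qm, int* lcp) {
  int j = 0;
  while (j < qm) {
    if (pos + j >= n) { if (lcp) *lcp = j; return -1; }
    int d = (int)g[pos + j] - (int)q[j];
    if (d != 0) { if (lcp) *lcp = j; return d < 0 ? -1 : 1; }
    ++j;
  }
  if (lcp) *lcp = qm;
  return 0;
}

// Half-open row range [sp, ep) of SSA rows (restricted to [lo, hi)) whose
// suffixes have q as a prefix.  Comparison is on-the-fly against the genome;
// no suffix strings are materialised.
static void range_search(const uint8_t* g, int n, const int* ssa, int D,
                         const uint8_t* q, int qm, int lo, int hi,
                         int* sp, int* ep) {
  int a = lo, b = hi;
  while (a < b) {
    int mid = a + (b - a) / 2;
    if (suf_cmp_q(g, n, (long long)ssa[mid] * D, q, qm, nullptr) < 0) a = mid + 1;
    else b = mid;
  }
  *sp = a;
  b = hi;
  while (a < b) {
    int mid = a + (b - a) / 2;
    if (suf_cmp_q(g, n, (long long)ssa[mid] * D, q, qm, nullptr) <= 0) a = mid + 1;
    else b = mid;
  }
  *ep = a;
}

// Longest matching prefix of q over the sampled suffixes.  On a miss it is the
// larger LCP of the two rows adjacent to the binary-search insertion point,
// which by sortedness equals the maximum LCP over all sampled suffixes.
static int prefix_len(const uint8_t* g, int n, const int* ssa, int S, int D,
                      const uint8_t* q, int qm) {
  int sp, ep;
  range_search(g, n, ssa, D, q, qm, 0, S, &sp, &ep);
  if (ep > sp) return qm;
  int L = 0, l = 0;
  if (sp > 0) { suf_cmp_q(g, n, (long long)ssa[sp - 1] * D, q, qm, &l); if (l > L) L = l; }
  if (sp < S) { suf_cmp_q(g, n, (long long)ssa[sp] * D, q, qm, &l); if (l > L) L = l; }
  return L;
}

static inline void table_bounds(const uint8_t* q, int qm, int K,
                                const int* tlo, const int* thi, int S,
                                int* lo, int* hi) {
  if (K <= 0 || qm < K || tlo == nullptr) { *lo = 0; *hi = S; return; }
  int c = 0;
  for (int j = 0; j < K; ++j) c = (c << 2) | q[j];
  *lo = tlo[c];
  *hi = thi[c];
}

// All exact occurrences of pat (head/tail decomposition over the D offsets).
// Lout, when requested, receives the pruning prefix used by the mismatch
// search: max over offsets of i + (tail neighbour LCP), or m as soon as any
// offset's tail range is non-empty.  This deliberately overestimates the true
// longest matching prefix; overestimates only cost extra candidates and can
// never lose an alignment.
static void exact_search(const uint8_t* g, int n, const int* ssa, int S,
                         int D, int K, const int* tlo, const int* thi,
                         const uint8_t* pat, int m,
                         std::vector<int>& starts, int* Lout) {
  int Lbest = 0;
  for (int i = 0; i < D && i < m; ++i) {
    const uint8_t* q = pat + i;
    int qm = m - i;
    int lo, hi;
    table_bounds(q, qm, K, tlo, thi, S, &lo, &hi);
    int sp, ep;
    range_search(g, n, ssa, D, q, qm, lo, hi, &sp, &ep);
    if (ep > sp) {
      Lbest = m;
      for (int r = sp; r < ep; ++r) {
        long long s = (long long)ssa[r] * D - i;
        if (s < 0) continue;
        bool ok = true;
        for (int j = 0; j < i; ++j)
          if (g[s + j] != pat[j]) { ok = false; break; }
        if (ok) starts.push_back((int)s);
      }
    } else if (Lout != nullptr && Lbest < m) {
      int cand = i + prefix_len(g, n, ssa, S, D, q, qm);
      if (cand > m) cand = m;
      if (cand > Lbest) Lbest = cand;
    }
  }
  std::sort(starts.begin(), starts.end());
  if (Lout) *Lout = Lbest;
}

// ---------------------------------------------------------------------------
// suffix array construction: prefix doubling, O(n log^2 n).  Rank -1 stands
// for "past the end", which realises the sentinel rule (shorter suffix first).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(RawVector codes) {
  int n = codes.size();
  if (n < 1) stop("empty genome");
  std::vector<int> sa(n), rk(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rk[i] = (int)codes[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      int ra = a + k < n ? rk[a + k] : -1;
      int rb = b + k < n ? rk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rk = tmp;
    if (rk[sa[n - 1]] == n - 1) break;
    if (k > n) break;  // unreachable safety stop
  }
  return IntegerVector(sa.begin(), sa.end());
}

static const int* opt_ptr(Nullable<IntegerVector>& x, IntegerVector& keep) {
  if (x.isNull()) return nullptr;
  keep = x.get();
  return INTEGER(keep);
}

// [[Rcpp::export]]
IntegerVector cpp_range_search(RawVector genome, IntegerVector ssa, int D,
                               int K, Nullable<IntegerVector> tab_lo,
                               Nullable<IntegerVector> tab_hi,
                               RawVector query, bool use_table) {
  int S = ssa.size(), n = genome.size(), qm = query.size();
  const uint8_t* g = RAW(genome);
  const uint8_t* q = RAW(query);
  int lo = 0, hi = S;
  IntegerVector tl, th;
  if (use_table) {
    const int* plo = opt_ptr(tab_lo, tl);
    const int* phi = opt_ptr(tab_hi, th);
    table_bounds(q, qm, K, plo, phi, S, &lo, &hi);
  }
  int sp, ep;
  range_search(g, n, INTEGER(ssa), D, q, qm, lo, hi, &sp, &ep);
  return IntegerVector::create(sp, ep);
}

// [[Rcpp::export]]
int cpp_longest_prefix(RawVector genome, IntegerVector ssa, int D,
                       RawVector query) {
  return prefix_len(RAW(genome), genome.size(), INTEGER(ssa), ssa.size(), D,
                    RAW(query), query.size());
}

// [[Rcpp::export]]
List cpp_exact_align(RawVector genome, IntegerVector ssa, int D, int K,
                     Nullable<IntegerVector> tab_lo,
                     Nullable<IntegerVector> tab_hi, RawVector pattern) {
  IntegerVector tl, th;
  const int* plo = opt_ptr(tab_lo, tl);
  const int* phi = opt_ptr(tab_hi, th);
  std::vector<int> starts;
  int L = 0;
  exact_search(RAW(genome), genome.size(), INTEGER(ssa), ssa.size(), D, K,
               plo, phi, RAW(pattern), pattern.size(), starts, &L);
  return List::create(_["starts"] = IntegerVector(starts.begin(), starts.end()),
                      _["L"] = L);
}

// ---------------------------------------------------------------------------
// rightmost k-mismatch search
// ---------------------------------------------------------------------------

// Order masks (ascending mismatch positions) by decreasing B: at the first
// differing slot the larger position wins; a list that is a strict prefix of
// the other precedes it.  Returns -1 / 0 / +1 (a before / equal / a after b).
static int mask_cmp(const std::vector<int>& a, const std::vector<int>& b) {
  size_t t = 0;
  for (;;) {
    bool ea = t >= a.size(), eb = t >= b.size();
    if (ea && eb) return 0;
    if (ea) return -1;
    if (eb) return 1;
    if (a[t] != b[t]) return a[t] > b[t] ? -1 : 1;
    ++t;
  }
}

struct KmHit {
  int start;
  std::vector<int> mask;
};

// Level-by-level generation: each candidate keeps its altered pattern, the
// (ascending) list of altered positions, and the failure prefix of its own
// exact search.  New alterations lie strictly right of the previous one and
// never beyond the parent's failure prefix L'.
// [[Rcpp::export]]
List cpp_k_mismatch(RawVector genome, IntegerVector ssa, int D, int K,
                    Nullable<IntegerVector> tab_lo,
                    Nullable<IntegerVector> tab_hi, RawVector pattern,
                    int k) {
  const uint8_t* g = RAW(genome);
  const uint8_t* pat0 = RAW(pattern);
  int n = genome.size(), S = ssa.size(), m = pattern.size();
  const int* sa = INTEGER(ssa);
  IntegerVector tl, th;
  const int* plo = opt_ptr(tab_lo, tl);
  const int* phi = opt_ptr(tab_hi, th);

  struct Cand {
    std::vector<uint8_t> pat;
    std::vector<int> alt;  // ascending
    int L;
  };

  std::vector<KmHit> hits;
  std::vector<Cand> frontier;

  {
    Cand root;
    root.pat.assign(pat0, pat0 + m);
    std::vector<int> st;
    exact_search(g, n, sa, S, D, K, plo, phi, root.pat.data(), m, st, &root.L);
    for (int s : st) hits.push_back(KmHit{s, {}});
    frontier.push_back(std::move(root));
  }

  for (int level = 1; level <= k; ++level) {
    std::vector<Cand> next;
    for (const Cand& par : frontier) {
      int floorp = par.alt.empty() ? -1 : par.alt.back();
      int pmax = std::min(par.L, m - 1);
      for (int p = pmax; p > floorp; --p) {
        uint8_t orig = pat0[p];
        for (uint8_t c = 0; c < 4; ++c) {
          if (c == orig) continue;
          Cand ch;
          ch.pat = par.pat;
          ch.pat[p] = c;
          ch.alt = par.alt;
          ch.alt.push_back(p);
          std::vector<int> st;
          int Lc = 0;
          exact_search(g, n, sa, S, D, K, plo, phi, ch.pat.data(), m, st, &Lc);
          for (int s : st) hits.push_back(KmHit{s, ch.alt});
          if (level < k) {
            ch.L = Lc;
            next.push_back(std::move(ch));
          }
        }
      }
    }
    frontier = std::move(next);
    Rcpp::checkUserInterrupt();
  }

  std::stable_sort(hits.begin(), hits.end(),
                   [](const KmHit& a, const KmHit& b) {
                     int c = mask_cmp(a.mask, b.mask);
                     if (c != 0) return c < 0;
                     return a.start < b.start;
                   });

  int H = (int)hits.size();
  IntegerVector starts(H);
  List masks(H);
  for (int i = 0; i < H; ++i) {
    starts[i] = hits[i].start;
    masks[i] = IntegerVector(hits[i].mask.begin(), hits[i].mask.end());
  }
  return List::create(_["starts"] = starts, _["masks"] = masks);
}
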