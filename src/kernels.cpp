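#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Global pairwise alignment, affine gaps (Gotoh). A gap of length L scores
// gap_open + L * gap_ext. Traceback preference at every cell: diagonal, then
// up (gap in b), then left (gap in a). Integer scores keep ties exact.
// ---------------------------------------------------------------------------

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_ext) {
  int n = (int)a.size(), m = (int)b.size();
  // state matrices: 0 = M (diag), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<int> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  // traceback: predecessor state for each cell/state
  std::vector<signed char> tbM((n + 1) * (m + 1), -1), tbX((n + 1) * (m + 1), -1),
      tbY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + gap_ext * i;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + gap_ext * j;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: prefer M, then X, then Y on ties
      int d0 = M[at(i - 1, j - 1)], d1 = X[at(i - 1, j - 1)], d2 = Y[at(i - 1, j - 1)];
      int best = d0; signed char who = 0;
      if (d1 > best) { best = d1; who = 1; }
      if (d2 > best) { best = d2; who = 2; }
      if (best > NEG) { M[at(i, j)] = best + s; tbM[at(i, j)] = who; }
      // X (consume a_i): open from M or extend X
      int xo = (M[at(i - 1, j)] > NEG) ? M[at(i - 1, j)] + gap_open + gap_ext : NEG;
      int xe = (X[at(i - 1, j)] > NEG) ? X[at(i - 1, j)] + gap_ext : NEG;
      if (xo >= xe && xo > NEG) { X[at(i, j)] = xo; tbX[at(i, j)] = 0; }
      else if (xe > NEG)        { X[at(i, j)] = xe; tbX[at(i, j)] = 1; }
      // Y (consume b_j): open from M or extend Y
      int yo = (M[at(i, j - 1)] > NEG) ? M[at(i, j - 1)] + gap_open + gap_ext : NEG;
      int ye = (Y[at(i, j - 1)] > NEG) ? Y[at(i, j - 1)] + gap_ext : NEG;
      if (yo >= ye && yo > NEG) { Y[at(i, j)] = yo; tbY[at(i, j)] = 0; }
      else if (ye > NEG)        { Y[at(i, j)] = ye; tbY[at(i, j)] = 2; }
    }
  }
  int fm = M[at(n, m)], fx = X[at(n, m)], fy = Y[at(n, m)];
  int state = 0, score = fm;
  if (fx > score) { score = fx; state = 1; }
  if (fy > score) { score = fy; state = 2; }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tbM[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tbX[at(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      signed char prev = tbY[at(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// ---------------------------------------------------------------------------
// Perfect SSR scanner. Reports every maximal perfect tandem run with a
// primitive motif meeting the period-specific unit threshold. Runs containing
// N never match. Span is truncated to whole units from the leftmost start.
// ---------------------------------------------------------------------------

static bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

static bool primitive_motif(const std::string& motif) {
  int p = (int)motif.size();
  for (int d = 1; d < p; ++d) {
    if (p % d != 0) continue;
    bool rep = true;
    for (int t = d; t < p && rep; ++t)
      if (motif[t] != motif[t - d]) rep = false;
    if (rep) return false;
  }
  return true;
}

// [[Rcpp::export]]
DataFrame ssr_scan_cpp(std::string s, int max_period, int min_mono, int min_multi) {
  int n = (int)s.size();
  std::vector<std::string> motifs;
  std::vector<int> periods, units, starts, ends;
  for (int p = 1; p <= max_period; ++p) {
    int x = 0;
    while (x + p < n) {
      // find next maximal run of positions with s[x] == s[x+p], bases only
      if (!(is_base(s[x]) && s[x] == s[x + p])) { ++x; continue; }
      int run_start = x;
      while (x + p < n && is_base(s[x]) && s[x] == s[x + p]) ++x;
      int run_len = x - run_start;          // matched positions
      int total = run_len + p;              // periodic stretch length
      int u = total / p;
      int thr = (p == 1) ? min_mono : min_multi;
      if (u >= thr) {
        std::string motif = s.substr(run_start, p);
        if (primitive_motif(motif)) {
          motifs.push_back(motif);
          periods.push_back(p);
          units.push_back(u);
          starts.push_back(run_start);
          ends.push_back(run_start + p * u);
        }
      }
    }
  }
  return DataFrame::create(_["motif"] = motifs, _["period"] = periods,
                           _["unit_count"] = units, _["start"] = starts,
                           _["end"] = ends, _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Inverted-repeat detection: k-mer seeding of the sequence against its
// reverse complement, one seed per anti-diagonal, greedy extension. Isolated
// mismatches are absorbed only when followed by a clean stretch, so exact
// planted repeats are recovered exactly.
// ---------------------------------------------------------------------------

static inline int code_of(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1; case 'G': return 2;
               case 'T': return 3; default: return -1; }
}
static inline char comp_of(char c) {
  switch (c) { case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C';
               case 'T': return 'A'; default: return 'N'; }
}

// [[Rcpp::export]]
List ir_scan_cpp(std::string s, int min_ir, double max_mm_frac, int k) {
  int n = (int)s.size();
  List none = List::create(_["found"] = false);
  if (n < 2 * min_ir || k > n) return none;
  const int MAXOCC = 32, CLEAN = 10;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> idx;
  idx.reserve(n * 2);
  { // index k-mers of s
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = code_of(s[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        auto& v = idx[h];
        if ((int)v.size() <= MAXOCC) v.push_back(i - k + 1);
      }
    }
  }
  std::string rc(n, 'N');
  for (int i = 0; i < n; ++i) rc[i] = comp_of(s[n - 1 - i]);
  std::unordered_map<long long, char> seen_diag;
  long long best_len = 0; int b_lo = -1, b_hi = -1; long long b_d = 0; int b_mm = 0;
  auto try_seed = [&](int j0, long long d) {
    // arm1 [lo, hi] in s, partner of u is v = d + k - 1 - u
    int lo = j0, hi = j0 + k - 1, mm = 0;
    // extend right
    while (true) {
      int nu = hi + 1; long long v = d + (long long)k - 1 - nu;
      if (v <= nu || v >= n || nu >= n) break;
      if (is_base(s[nu]) && s[nu] == comp_of(s[(int)v])) { hi = nu; continue; }
      // absorb a single mismatch only if budget allows and next CLEAN match
      int len = hi - lo + 1;
      int budget = (int)(max_mm_frac * (double)len);
      if (mm + 1 > budget) break;
      bool clean = true;
      for (int t = 1; t <= CLEAN; ++t) {
        int uu = nu + t; long long vv = d + (long long)k - 1 - uu;
        if (vv <= uu || vv >= n || uu >= n ||
            !(is_base(s[uu]) && s[uu] == comp_of(s[(int)vv]))) { clean = false; break; }
      }
      if (!clean) break;
      ++mm; hi = nu;
    }
    // extend left
    while (true) {
      int nu = lo - 1; long long v = d + (long long)k - 1 - nu;
      if (nu < 0 || v >= n || v <= hi) break;
      if (is_base(s[nu]) && s[nu] == comp_of(s[(int)v])) { lo = nu; continue; }
      int len = hi - lo + 1;
      int budget = (int)(max_mm_frac * (double)len);
      if (mm + 1 > budget) break;
      bool clean = true;
      for (int t = 1; t <= CLEAN; ++t) {
        int uu = nu - t; long long vv = d + (long long)k - 1 - uu;
        if (uu < 0 || vv >= n ||
            !(is_base(s[uu]) && s[uu] == comp_of(s[(int)vv]))) { clean = false; break; }
      }
      if (!clean) break;
      ++mm; lo = nu;
    }
    long long len = hi - lo + 1;
    if (len >= min_ir &&
        (len > best_len || (len == best_len && lo < b_lo))) {
      best_len = len; b_lo = lo; b_hi = hi; b_d = d; b_mm = mm;
    }
  };
  { // roll over rc, look up in s index
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = code_of(rc[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      int p = i - k + 1;                 // start of k-mer in rc
      int m = n - p - k;                 // corresponding arm start in s
      auto it = idx.find(h);
      if (it == idx.end() || (int)it->second.size() > MAXOCC) continue;
      for (int j : it->second) {
        if (j == m) continue;            // self (palindromic center)
        int lo1 = std::min(j, m);
        long long d = (long long)j + m;
        long long key = d;
        auto sd = seen_diag.find(key);
        if (sd != seen_diag.end()) continue;
        seen_diag[key] = 1;
        try_seed(lo1, d);
      }
    }
  }
  if (best_len < min_ir) return none;
  int a_start = b_lo, a_end = b_hi + 1;                      // half-open
  int bs = (int)(b_d + k - 1 - b_hi), be = (int)(b_d + k - 1 - b_lo) + 1;
  return List::create(_["found"] = true, _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = bs, _["b_end"] = be,
                      _["length"] = (int)best_len, _["mismatches"] = b_mm);
}

// ---------------------------------------------------------------------------
// Exact two-sided permutation p-value for Spearman's statistic. Enumerates
// distinct arrangements of the (mid)ranks of y; each arrangement carries
// equal weight under the permutation null.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double spearman_perm_p_cpp(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  double sx = 0, sy = 0;
  for (int i = 0; i < n; ++i) { sx += rx[i]; sy += ry[i]; }
  double center = sx * sy / n;
  double s_obs = 0;
  for (int i = 0; i < n; ++i) s_obs += rx[i] * ry[i];
  double crit = std::fabs(s_obs - center) - 1e-9;
  std::vector<double> perm(ry.begin(), ry.end());
  std::sort(perm.begin(), perm.end());
  long long total = 0, extreme = 0;
  do {
    double s = 0;
    for (int i = 0; i < n; ++i) s += rx[i] * perm[i];
    ++total;
    if (std::fabs(s - center) >= crit) ++extreme;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return (double)extreme / (double)total;
}
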