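#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 61-bit Mersenne prime modulus for the Karp-Rabin rolling hash. The odd
// multiplier is fixed so that parses are reproducible across runs and
// machines; it is configuration, not a secret.
static const uint64_t KR_MOD = (uint64_t(1) << 61) - 1;
static const uint64_t KR_BASE = 0x100000001b3ULL; // odd, > any symbol code

static inline uint64_t mulmod61(uint64_t a, uint64_t b) {
  __uint128_t z = ( __uint128_t ) a * b;
  uint64_t lo = (uint64_t)(z & KR_MOD);
  uint64_t hi = (uint64_t)(z >> 61);
  uint64_t s = lo + hi;
  if (s >= KR_MOD) s -= KR_MOD;
  return s;
}

// End positions (1-based) of all length-w windows whose KR hash is
// divisible by the modulus p.
// [[Rcpp::export(name = ".pm_trigger_ends")]]
IntegerVector pm_trigger_ends(IntegerVector s, int w, int p) {
  int n = s.size();
  std::vector<int> out;
  if (n < w || w < 1 || p < 1) return IntegerVector(0);
  // power = KR_BASE^(w-1) mod KR_MOD
  uint64_t power = 1;
  for (int k = 0; k < w - 1; ++k) power = mulmod61(power, KR_BASE);
  uint64_t h = 0;
  for (int i = 0; i < w; ++i)
    h = (mulmod61(h, KR_BASE) + (uint64_t)s[i]) % KR_MOD;
  if (h % (uint64_t)p == 0) out.push_back(w);
  for (int i = w; i < n; ++i) {
    uint64_t drop = mulmod61((uint64_t)s[i - w], power);
    h = (h + KR_MOD - drop) % KR_MOD;
    h = (mulmod61(h, KR_BASE) + (uint64_t)s[i]) % KR_MOD;
    if (h % (uint64_t)p == 0) out.push_back(i + 1);
  }
  return wrap(out);
}

// Kasai's algorithm. s: symbol codes (sentinels already embedded, all
// values distinct where required), sa: 1-based suffix start positions.
// Returns LCP with LCP[1] = -1, LCP[i] = lcp(suffix sa[i-1], suffix sa[i]).
// [[Rcpp::export(name = ".pm_kasai")]]
IntegerVector pm_kasai(IntegerVector s, IntegerVector sa) {
  int n = s.size();
  IntegerVector lcp(n);
  std::vector<int> rank(n);
  for (int i = 0; i < n; ++i) rank[sa[i] - 1] = i;
  int h = 0;
  lcp[0] = -1;
  for (int i = 0; i < n; ++i) {
    int r = rank[i];
    if (r > 0) {
      int j = sa[r - 1] - 1;
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[r] = h;
      if (h > 0) --h;
    } else {
      lcp[r] = -1;
      h = 0;
    }
  }
  return lcp;
}

// Stack-based enumeration of all lcp-intervals of an LCP array
// (LCP[1] = -1; a virtual LCP[n+1] = -1 closes everything). Emits one row
// (ell, lb, rb) per interval with ell >= min_ell and width >= 2.
// [[Rcpp::export(name = ".pm_lcp_intervals")]]
IntegerMatrix pm_lcp_intervals(IntegerVector lcp, int min_ell) {
  int n = lcp.size();
  std::vector<int> st_ell, st_lb;
  std::vector<int> res_ell, res_lb, res_rb;
  st_ell.push_back(0); st_lb.push_back(1);
  for (int i = 2; i <= n + 1; ++i) {
    int lb = i - 1;
    int cur = (i <= n) ? lcp[i - 1] : -1;
    while (!st_ell.empty() && cur < st_ell.back()) {
      int ell = st_ell.back(), l = st_lb.back();
      st_ell.pop_back(); st_lb.pop_back();
      int rb = i - 1;
      if (ell >= min_ell && rb > l) {
        res_ell.push_back(ell); res_lb.push_back(l); res_rb.push_back(rb);
      }
      lb = l;
    }
    if (st_ell.empty() || cur > st_ell.back()) {
      st_ell.push_back(cur); st_lb.push_back(lb);
    }
  }
  int k = res_ell.size();
  IntegerMatrix out(k, 3);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = res_ell[i]; out(i, 1) = res_lb[i]; out(i, 2) = res_rb[i];
  }
  colnames(out) = CharacterVector::create("ell", "lb", "rb");
  return out;
}

// Unit-cost global alignment (match 0, mismatch 1, indel 1) restricted to a
// diagonal band, with band doubling (Ukkonen): a computed cost <= band is
// provably optimal. Returns cost = -1 when no optimum was certified within
// band_max (caller falls back to an unaligned layout).
// a_idx/b_idx: 1-based source positions per alignment column, 0 = gap.
// [[Rcpp::export(name = ".pm_edit_align")]]
List pm_edit_align(IntegerVector a, IntegerVector b, int band_max) {
  const int INF = INT_MAX / 4;
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) {
    IntegerVector ai(n + m), bi(n + m);
    for (int i = 0; i < n; ++i) { ai[i] = i + 1; bi[i] = 0; }
    for (int j = 0; j < m; ++j) { ai[n + j] = 0; bi[n + j] = j + 1; }
    return List::create(_["cost"] = n + m, _["a_idx"] = ai, _["b_idx"] = bi);
  }
  int band = std::abs(n - m) + 16;
  int maxdim = std::max(n, m);
  while (true) {
    if (band > band_max && band_max < maxdim)
      return List::create(_["cost"] = -1,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    if (band > maxdim) band = maxdim;
    long long width = 2LL * band + 1;
    if ((double)(n + 1) * width > 6e8) // refuse absurd traceback tables
      return List::create(_["cost"] = -1,
                          _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    std::vector<uint8_t> ops((size_t)(n + 1) * width, 0);
    std::vector<int> prev(width, INF), cur(width, INF);
    // row i: valid j in [max(0,i-band), min(m,i+band)], col = j-(i-band)
    for (int j = 0; j <= std::min(m, band); ++j) {
      prev[j + band] = j;                       // row 0: all inserts
      ops[(size_t)0 * width + j + band] = 1;
    }
    for (int i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), INF);
      int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
      for (int j = jlo; j <= jhi; ++j) {
        int col = j - (i - band);
        int best = INF; uint8_t op = 0;
        // diagonal: prev row col index = (j-1)-(i-1-band) = col
        if (j > 0 && prev[col] < INF) {
          int d = prev[col] + (a[i - 1] != b[j - 1] ? 1 : 0);
          if (d < best) { best = d; op = 3; }
        }
        // up (consume a, gap in b): prev row col index = j-(i-1-band)=col+1
        if (col + 1 < width && prev[col + 1] < INF) {
          int d = prev[col + 1] + 1;
          if (d < best) { best = d; op = 2; }
        }
        // left (consume b, gap in a): same row, col-1
        if (col - 1 >= 0 && cur[col - 1] < INF) {
          int d = cur[col - 1] + 1;
          if (d < best) { best = d; op = 1; }
        }
        cur[col] = best;
        ops[(size_t)i * width + col] = op;
      }
      std::swap(prev, cur);
    }
    int final_col = m - (n - band);
    int cost = (final_col >= 0 && final_col < width) ? prev[final_col] : INF;
    if (cost <= band || band >= maxdim) {
      if (cost >= INF)
        return List::create(_["cost"] = -1,
                            _["a_idx"] = IntegerVector(0),
                            _["b_idx"] = IntegerVector(0));
      // traceback
      std::vector<int> ai, bi;
      int i = n, j = m;
      while (i > 0 || j > 0) {
        int col = j - (i - band);
        uint8_t op = ops[(size_t)i * width + col];
        if (op == 3) { ai.push_back(i); bi.push_back(j); --i; --j; }
        else if (op == 2) { ai.push_back(i); bi.push_back(0); --i; }
        else { ai.push_back(0); bi.push_back(j); --j; }
      }
      std::reverse(ai.begin(), ai.end());
      std::reverse(bi.begin(), bi.end());
      return List::create(_["cost"] = cost, _["a_idx"] = wrap(ai),
                          _["b_idx"] = wrap(bi));
    }
    band *= 2;
  }
}

// Unit-cost edit distance only (band-doubling, no traceback); -1 if not
// certified within band_max.
// [[Rcpp::export(name = ".pm_edit_cost")]]
int pm_edit_cost(IntegerVector a, IntegerVector b, int band_max) {
  const int INF = INT_MAX / 4;
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return n + m;
  int band = std::abs(n - m) + 16;
  int maxdim = std::max(n, m);
  while (true) {
    if (band > band_max && band_max < maxdim) return -1;
    if (band > maxdim) band = maxdim;
    int width = 2 * band + 1;
    std::vector<int> prev(width, INF), cur(width, INF);
    for (int j = 0; j <= std::min(m, band); ++j) prev[j + band] = j;
    for (int i = 1; i <= n; ++i) {
      std::fill(cur.begin(), cur.end(), INF);
      int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
      for (int j = jlo; j <= jhi; ++j) {
        int col = j - (i - band);
        int best = INF;
        if (j > 0 && prev[col] < INF) {
          int d = prev[col] + (a[i - 1] != b[j - 1] ? 1 : 0);
          if (d < best) best = d;
        }
        if (col + 1 < width && prev[col + 1] < INF) {
          int d = prev[col + 1] + 1;
          if (d < best) best = d;
        }
        if (col - 1 >= 0 && cur[col - 1] < INF) {
          int d = cur[col - 1] + 1;
          if (d < best) best = d;
        }
        cur[col] = best;
      }
      std::swap(prev, cur);
    }
    int final_col = m - (n - band);
    int cost = (final_col >= 0 && final_col < width) ? prev[final_col] : INF;
    if ((cost <= band || band >= maxdim) && cost < INF) return cost;
    if (band >= maxdim) return -1;
    band *= 2;
  }
}
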