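#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Constrained miRNA/miRNA* duplex alignment.
//
// The query is aligned against the reverse of the partner under a pairing
// alphabet: A-T/U, C-G and the G:U wobble count as paired, anything else
// aligned is a mismatch. Gap runs are bulges. A global alignment is
// required (Dicer-style overhangs surface as short terminal gap runs) with
//   mismatches        <= mismatch_max
//   every gap run     <= bulge_max
//   total gap columns <= gap_total_max.
// For aligned columns A and total gaps t, A = (m + n - t) / 2 and
// pairs = A - mismatches, so maximising pairs is minimising mm + t/2;
// the DP minimises mismatches for every reachable total-gap count and the
// best feasible combination is selected afterwards.

static inline bool can_pair(char a, char b) {
  if (a == 'A' && b == 'T') return true;
  if (a == 'T' && b == 'A') return true;
  if (a == 'C' && b == 'G') return true;
  if (a == 'G' && b == 'C') return true;
  if (a == 'G' && b == 'T') return true;   // G:U wobble
  if (a == 'T' && b == 'G') return true;
  return false;
}

static const int BAD = 127;

struct DuplexResult {
  bool feasible;
  int pairs, mismatches, gap_total, max_bulge;
  std::vector<int> bulges;
};

// `b` is the partner sequence already reversed
static DuplexResult duplex_core(const std::string &x, const std::string &b,
                                int mismatch_max, int bulge_max,
                                int gap_total_max) {
  DuplexResult res;
  res.feasible = false;
  res.pairs = 0; res.mismatches = -1; res.gap_total = -1; res.max_bulge = 0;
  const int m = x.size();
  const int n = b.size();
  const int G = gap_total_max, B = bulge_max, NG = 2 * B + 1;
  if (std::abs(m - n) > G) return res;

  static std::vector<signed char> V;   // reused across calls
  V.assign((size_t)(m + 1) * (n + 1) * (G + 1) * NG, BAD);
  auto at = [&](int i, int j, int t, int g) -> size_t {
    return (((size_t)i * (n + 1) + j) * (G + 1) + t) * NG + g;
  };
  V[at(0, 0, 0, 0)] = 0;

  for (int i = 0; i <= m; ++i) {
    int jlo = std::max(0, i - G), jhi = std::min(n, i + G);
    for (int j = jlo; j <= jhi; ++j) {
      // total gaps and i-j always share parity on any reachable state
      for (int t = std::abs(i - j); t <= G; t += 2) {
        for (int g = 0; g < NG; ++g) {
          if (g != 0 && (g <= B ? g : g - B) > t) continue; // run <= gaps
          int v = V[at(i, j, t, g)];
          if (v >= BAD) continue;
          if (i < m && j < n) {
            int nv = v + (can_pair(x[i], b[j]) ? 0 : 1);
            if (nv <= mismatch_max && nv < V[at(i + 1, j + 1, t, 0)])
              V[at(i + 1, j + 1, t, 0)] = (signed char)nv;
          }
          if (i < m && t < G) {   // consume query base alone
            int r = (g >= 1 && g <= B) ? g + 1 : 1;
            if (r <= B && v < V[at(i + 1, j, t + 1, r)])
              V[at(i + 1, j, t + 1, r)] = (signed char)v;
          }
          if (j < n && t < G) {   // consume partner base alone
            int r = (g > B) ? g - B + 1 : 1;
            if (r <= B && v < V[at(i, j + 1, t + 1, B + r)])
              V[at(i, j + 1, t + 1, B + r)] = (signed char)v;
          }
        }
      }
    }
  }

  int best_t = -1, best_g = -1, best_mm = BAD, best_pairs = -1;
  for (int t = std::abs(m - n); t <= G; ++t) {
    if ((m + n - t) % 2) continue;
    int A = (m + n - t) / 2;
    for (int g = 0; g < NG; ++g) {
      int v = V[at(m, n, t, g)];
      if (v > mismatch_max) continue;
      int pairs = A - v;
      if (pairs > best_pairs || (pairs == best_pairs && v < best_mm)) {
        best_pairs = pairs; best_mm = v; best_t = t; best_g = g;
      }
    }
  }
  if (best_pairs < 0) return res;

  // traceback to recover bulge run lengths
  std::vector<int> runs;
  {
    int i = m, j = n, t = best_t, g = best_g, v = best_mm, cur = 0;
    while (i > 0 || j > 0) {
      if (g >= 1 && g <= B) {           // arrived via query-alone column
        int pg = g - 1;
        ++cur;
        if (pg == 0) {
          // run of length 1 begins after a non-query-gap state
          int fg = -1;
          for (int cand = 0; cand < NG; ++cand) {
            if (cand >= 1 && cand <= B) continue;
            if (V[at(i - 1, j, t - 1, cand)] == v) { fg = cand; break; }
          }
          if (fg < 0) stop("duplex traceback failed");
          runs.push_back(cur); cur = 0;
          --i; --t; g = fg;
        } else {
          --i; --t; g = pg;
        }
      } else if (g > B) {               // arrived via partner-alone column
        int r = g - B;
        ++cur;
        if (r == 1) {
          int fg = -1;
          for (int cand = 0; cand < NG; ++cand) {
            if (cand > B) continue;
            if (V[at(i, j - 1, t - 1, cand)] == v) { fg = cand; break; }
          }
          if (fg < 0) stop("duplex traceback failed");
          runs.push_back(cur); cur = 0;
          --j; --t; g = fg;
        } else {
          --j; --t; g = B + r - 1;
        }
      } else {                          // aligned column
        int cost = can_pair(x[i - 1], b[j - 1]) ? 0 : 1;
        int pv = v - cost;
        int fg = -1;
        for (int cand = 0; cand < NG; ++cand)
          if (V[at(i - 1, j - 1, t, cand)] == pv) { fg = cand; break; }
        if (fg < 0) stop("duplex traceback failed");   // internal error
        --i; --j; v = pv; g = fg;
      }
    }
    if (cur > 0) runs.push_back(cur);
  }

  res.feasible = true;
  res.pairs = best_pairs;
  res.mismatches = best_mm;
  res.gap_total = best_t;
  res.bulges = runs;
  for (int r : runs) res.max_bulge = std::max(res.max_bulge, r);
  return res;
}

// banded upper bound on achievable paired columns; exact from above so
// it can only prune infeasible pairs, never drop feasible ones
static int pairs_upper_bound(const std::string &x, const std::string &b,
                             int G) {
  const int m = x.size();
  const int n = b.size();
  std::vector<short> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - G), jhi = std::min(n, i + G);
    for (int j = jlo; j <= jhi; ++j) {
      short best = std::max(prev[j], cur[j - 1]);
      short diag = prev[j - 1];
      if (can_pair(x[i - 1], b[j - 1])) diag = (short)(diag + 1);
      if (diag > best) best = diag;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string x, std::string y, int mismatch_max,
                      int bulge_max, int gap_total_max) {
  std::string b(y.rbegin(), y.rend());
  DuplexResult r = duplex_core(x, b, mismatch_max, bulge_max,
                               gap_total_max);
  if (!r.feasible) {
    return List::create(_["feasible"] = false, _["pairs"] = 0,
                        _["mismatches"] = NA_INTEGER,
                        _["gap_total"] = NA_INTEGER,
                        _["bulges"] = IntegerVector(0));
  }
  return List::create(_["feasible"] = true, _["pairs"] = r.pairs,
                      _["mismatches"] = r.mismatches,
                      _["gap_total"] = r.gap_total,
                      _["bulges"] = wrap(r.bulges));
}

// [[Rcpp::export(name = ".duplex_pairs_ub_cpp")]]
int duplex_pairs_ub_cpp(std::string x, std::string y, int gap_total_max) {
  std::string b(y.rbegin(), y.rend());
  return pairs_upper_bound(x, b, gap_total_max);
}

// All-against-dominant duplex pair search. Sequences must already be
// length-filtered; `dominant` marks tags satisfying the read floor. A
// pair of two dominants is reported once (lower index scanned first).
// [[Rcpp::export(name = ".find_duplex_pairs_cpp")]]
DataFrame find_duplex_pairs_cpp(CharacterVector seqs, LogicalVector dominant,
                                int mismatch_max, int bulge_max,
                                int gap_total_max) {
  const int n = seqs.size();
  std::vector<std::string> s(n), srev(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    srev[i] = std::string(s[i].rbegin(), s[i].rend());
  }
  std::vector<int> out_d, out_p, out_mm, out_pairs, out_gaps, out_bulge;
  for (int d = 0; d < n; ++d) {
    if (!dominant[d]) continue;
    const int m = s[d].size();
    for (int p = 0; p < n; ++p) {
      if (p == d) continue;
      if (dominant[p] && p < d) continue;   // already scanned
      const int ln = s[p].size();
      if (std::abs(m - ln) > gap_total_max) continue;
      int floor_pairs =
        (m + ln - gap_total_max + 1) / 2 - mismatch_max;
      if (pairs_upper_bound(s[d], srev[p], gap_total_max) < floor_pairs)
        continue;
      DuplexResult r = duplex_core(s[d], srev[p], mismatch_max, bulge_max,
                                   gap_total_max);
      if (!r.feasible) continue;
      out_d.push_back(d + 1);
      out_p.push_back(p + 1);
      out_mm.push_back(r.mismatches);
      out_pairs.push_back(r.pairs);
      out_gaps.push_back(r.gap_total);
      out_bulge.push_back(r.max_bulge);
    }
  }
  return DataFrame::create(_["dom"] = out_d, _["partner"] = out_p,
                           _["mismatches"] = out_mm, _["pairs"] = out_pairs,
                           _["gap_total"] = out_gaps,
                           _["max_bulge"] = out_bulge,
                           _["stringsAsFactors"] = false);
}
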