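#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Single-hairpin minimum-free-energy folding.
//
// The structure class searched is the one a pre-miRNA stem-loop lives in:
// a single chain of nested pairs (i1,j1) > (i2,j2) > ... closed by one
// hairpin loop -- no multiloops, no pseudoknots. V(i,j) is the MFE of the
// fragment i..j given that i pairs j; the global MFE is the best V over
// all pairable (i,j), or 0 (open chain) if nothing is stabilising.

static const double INF = 1e9;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// AU=1 CG=2 GC=3 UA=4 GU=5 UG=6, 0 = not pairable
static inline int pair_code(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct FoldParams {
  double stack[6][6];
  std::vector<double> hairpin, bulge, internal;
  double asym, asym_max;
  int max_interior, min_hairpin;
};

static FoldParams read_params(NumericMatrix stack, NumericVector hairpin,
                              NumericVector bulge, NumericVector internal,
                              double asym, double asym_max,
                              int max_interior, int min_hairpin) {
  FoldParams p;
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) p.stack[i][j] = stack(i, j);
  p.hairpin = as<std::vector<double> >(hairpin);
  p.bulge = as<std::vector<double> >(bulge);
  p.internal = as<std::vector<double> >(internal);
  p.asym = asym; p.asym_max = asym_max;
  p.max_interior = max_interior; p.min_hairpin = min_hairpin;
  return p;
}

// Jacobson-Stockmayer size extrapolation beyond the tabulated range
static inline double extrapolate(double last, int tab_max, int size) {
  // 1.75 * R * T at 37 C = 1.079 kcal/mol
  return last + 1.079 * std::log((double)size / (double)tab_max);
}

// MFE fold; fills `pairs` (0-based partner or -1) and returns dG
static double fold_core(const std::string &seq, const FoldParams &P,
                        std::vector<int> &pairs) {
  const int n = seq.size();
  pairs.assign(n, -1);
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_code(seq[i]);
    if (s[i] < 0)
      stop("non-ACGU/T character in sequence at position %d", i + 1);
  }
  auto hp_energy = [&](int size) -> double {
    if (size < P.min_hairpin) return INF;
    if (size <= (int)P.hairpin.size() + 2) return P.hairpin[size - 3];
    return extrapolate(P.hairpin.back(), P.hairpin.size() + 2, size);
  };
  auto bulge_energy = [&](int size) -> double {
    if (size <= (int)P.bulge.size()) return P.bulge[size - 1];
    return extrapolate(P.bulge.back(), P.bulge.size(), size);
  };
  auto internal_energy = [&](int size) -> double {
    if (size <= (int)P.internal.size() + 1) return P.internal[size - 2];
    return extrapolate(P.internal.back(), P.internal.size() + 1, size);
  };

  if (n < P.min_hairpin + 2) return 0.0;

  std::vector<double> V((size_t)n * n, INF);
  std::vector<int> tk((size_t)n * n, -1), tl((size_t)n * n, -1);
  auto at = [&](int i, int j) -> size_t { return (size_t)i * n + j; };

  for (int span = P.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = pair_code(s[i], s[j]);
      if (!pij) continue;
      double best = hp_energy(j - i - 1);
      int bk = -1, bl = -1;
      bool best_is_hairpin = true;
      // interior candidates, k ascending then l descending: ties resolve
      // to the 5'-most, pair-richest continuation
      int kmax = std::min(i + P.max_interior + 1, j - P.min_hairpin - 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int n1 = k - i - 1;
        int lmin = std::max(k + P.min_hairpin + 1,
                            j - 1 - (P.max_interior - n1));
        for (int l = j - 1; l >= lmin; --l) {
          int pkl = pair_code(s[k], s[l]);
          if (!pkl) continue;
          if (V[at(k, l)] >= INF) continue;
          int n2 = j - l - 1;
          double loop;
          if (n1 == 0 && n2 == 0) {
            loop = P.stack[pij - 1][pkl - 1];
          } else if (n1 == 0 || n2 == 0) {
            int nb = n1 + n2;
            loop = bulge_energy(nb);
            if (nb == 1) loop += P.stack[pij - 1][pkl - 1];
          } else {
            double ap = P.asym * std::abs(n1 - n2);
            loop = internal_energy(n1 + n2) + std::min(ap, P.asym_max);
          }
          double e = loop + V[at(k, l)];
          if (e < best - 1e-9 || (e < best + 1e-9 && best_is_hairpin)) {
            best = std::min(best, e);
            bk = k; bl = l;
            best_is_hairpin = false;
          }
        }
      }
      V[at(i, j)] = best;
      tk[at(i, j)] = bk;
      tl[at(i, j)] = bl;
    }
  }

  double mfe = 0.0;
  int oi = -1, oj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = n - 1; j > i; --j) {
      double v = V[at(i, j)];
      if (v < mfe - 1e-9) { mfe = v; oi = i; oj = j; }
    }
  }
  if (oi < 0) return 0.0;
  int i = oi, j = oj;
  while (i >= 0) {
    pairs[i] = j; pairs[j] = i;
    int k = tk[at(i, j)], l = tl[at(i, j)];
    i = k; j = l;
  }
  return mfe;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericMatrix stack,
                  NumericVector hairpin, NumericVector bulge,
                  NumericVector internal, double asym, double asym_max,
                  int max_interior, int min_hairpin) {
  FoldParams P = read_params(stack, hairpin, bulge, internal, asym,
                             asym_max, max_interior, min_hairpin);
  std::vector<int> pr;
  double dg = fold_core(seq, P, pr);
  const int n = seq.size();
  IntegerVector pairs(n, 0);
  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pr[i] >= 0) {
      pairs[i] = pr[i] + 1;
      db[i] = (pr[i] > i) ? '(' : ')';
    }
  }
  return List::create(_["dg"] = dg, _["structure"] = db, _["pairs"] = pairs);
}

// Batch linker-joining and folding of duplex candidate pairs: each pair
// is joined in both orders, the lower-energy order kept, and the
// fraction of dominant bases paired to partner bases measured on the
// MFE structure.
// [[Rcpp::export(name = ".join_fold_batch_cpp")]]
List join_fold_batch_cpp(CharacterVector dominants, CharacterVector partners,
                         std::string linker, NumericMatrix stack,
                         NumericVector hairpin, NumericVector bulge,
                         NumericVector internal, double asym,
                         double asym_max, int max_interior,
                         int min_hairpin) {
  FoldParams P = read_params(stack, hairpin, bulge, internal, asym,
                             asym_max, max_interior, min_hairpin);
  const int n = dominants.size();
  NumericVector dg(n), frac(n);
  CharacterVector joined(n), structure(n);
  std::vector<int> pr1, pr2;
  for (int q = 0; q < n; ++q) {
    std::string d = as<std::string>(dominants[q]);
    std::string p = as<std::string>(partners[q]);
    std::string j1 = d + linker + p;
    std::string j2 = p + linker + d;
    double e1 = fold_core(j1, P, pr1);
    double e2 = fold_core(j2, P, pr2);
    bool first = e1 <= e2;
    const std::string &js = first ? j1 : j2;
    const std::vector<int> &pr = first ? pr1 : pr2;
    // dominant occupies the head of j1, the tail of j2
    int d0 = first ? 0 : (int)(p.size() + linker.size());
    int o0 = first ? (int)(d.size() + linker.size()) : 0;
    int olen = (int)p.size();
    int paired_to_partner = 0;
    for (int i = 0; i < (int)d.size(); ++i) {
      int mate = pr[d0 + i];
      if (mate >= o0 && mate < o0 + olen) ++paired_to_partner;
    }
    dg[q] = first ? e1 : e2;
    frac[q] = d.size() ? (double)paired_to_partner / d.size() : 0.0;
    joined[q] = js;
    std::string db(js.size(), '.');
    for (size_t i = 0; i < js.size(); ++i)
      if (pr[i] >= 0) db[i] = (pr[i] > (int)i) ? '(' : ')';
    structure[q] = db;
  }
  return List::create(_["joined"] = joined, _["dg"] = dg,
                      _["structure"] = structure,
                      _["pair_fraction"] = frac);
}
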