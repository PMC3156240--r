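#include <Rcpp.h>
using namespace Rcpp;

// Tolerance-rule matcher for assigning tags to known mature miRNAs.
// A tag matches a reference mature when, at some ungapped 5' offset
// within +/- max_shift and with overall length difference <= len_diff_max,
// the overlap shows either
//   - no mismatches, or
//   - at most internal_mm_max mismatches anywhere, or
//   - at most end_mm_max mismatches all confined to the last 2 nt of the
//     tag's 3' end
// (end-variation outside the overlap is isomiR length fluctuation and is
// not a mismatch). Each tag is assigned to at most one reference: fewest
// mismatches, then smallest length difference, then lowest reference
// index (callers order references lexicographically by id).

// [[Rcpp::export(name = ".assign_mature_cpp")]]
DataFrame assign_mature_cpp(CharacterVector tags, CharacterVector refs,
                            int max_shift, int len_diff_max,
                            int end_mm_max, int internal_mm_max) {
  const int nt = tags.size(), nr = refs.size();
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);

  IntegerVector best_ref(nt, 0), best_mm(nt, NA_INTEGER),
      best_ld(nt, NA_INTEGER);

  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    const int lt = tag.size();
    int bmm = 1000, bld = 1000, bref = 0;
    for (int r = 0; r < nr; ++r) {
      const std::string &ref = rs[r];
      const int lr = ref.size();
      const int ld = std::abs(lt - lr);
      if (ld > len_diff_max) continue;
      int ref_best = 1000;
      for (int s = -max_shift; s <= max_shift; ++s) {
        // tag position i (0-based) aligns ref position i + s
        int mm = 0;
        bool end_only = true;
        for (int i = 0; i < lt; ++i) {
          int rp = i + s;
          if (rp < 0 || rp >= lr) continue;      // isomiR overhang
          if (tag[i] != ref[rp]) {
            ++mm;
            if (i < lt - 2) end_only = false;
          }
        }
        bool pass = (mm == 0) || (mm <= internal_mm_max) ||
                    (mm <= end_mm_max && end_only);
        if (pass && mm < ref_best) ref_best = mm;
      }
      if (ref_best < 1000) {
        if (ref_best < bmm || (ref_best == bmm && ld < bld)) {
          bmm = ref_best; bld = ld; bref = r + 1;
        }
      }
    }
    if (bref > 0) {
      best_ref[t] = bref;
      best_mm[t] = bmm;
      best_ld[t] = bld;
    }
  }
  return DataFrame::create(_["ref"] = best_ref, _["mismatches"] = best_mm,
                           _["len_diff"] = best_ld,
                           _["stringsAsFactors"] = false);
}
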