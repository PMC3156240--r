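#include <Rcpp.h>
#include <unordered_map>
#include <set>
using namespace Rcpp;

// Ungapped all-hits read mapping at Hamming distance <= max_mismatch,
// via an exact k-mer seed index. With max_mismatch = 1 a tag of length L
// always retains an intact k-mer when k <= ceil((L-1)/2), so the index
// only prunes and never misses a hit (the R wrapper enforces the bound).

static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".map_tags_cpp")]]
DataFrame map_tags_cpp(CharacterVector tags, std::string genome, int k,
                       int max_mismatch) {
  const int n = genome.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  index.reserve(n);
  if (n >= k) {
    uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      int c = code(genome[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & mask;
      if (++run >= k) index[key].push_back(i - k + 1);
    }
  }

  std::vector<int> out_tag, out_start, out_mm;
  std::vector<char> out_strand;

  for (int t = 0; t < tags.size(); ++t) {
    std::string fwd = as<std::string>(tags[t]);
    const int len = fwd.size();
    if (len > n || len < k) continue;
    std::string rev(len, 'N');
    for (int i = 0; i < len; ++i) rev[i] = comp(fwd[len - 1 - i]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      std::set<int> cand;
      uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
      int run = 0;
      for (int i = 0; i < len; ++i) {
        int c = code(q[i]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | c) & mask;
        if (++run >= k) {
          auto it = index.find(key);
          if (it != index.end()) {
            int off = i - k + 1;
            for (int p : it->second) {
              int start = p - off;
              if (start >= 0 && start + len <= n) cand.insert(start);
            }
          }
        }
      }
      for (int start : cand) {
        int mm = 0;
        for (int i = 0; i < len; ++i) {
          if (q[i] != genome[start + i] && ++mm > max_mismatch) break;
        }
        if (mm <= max_mismatch) {
          out_tag.push_back(t + 1);
          out_start.push_back(start);
          out_strand.push_back(strand == 0 ? '+' : '-');
          out_mm.push_back(mm);
        }
      }
    }
  }

  CharacterVector strand_out(out_strand.size());
  for (size_t i = 0; i < out_strand.size(); ++i)
    strand_out[i] = std::string(1, out_strand[i]);
  return DataFrame::create(_["tag"] = out_tag, _["start"] = out_start,
                           _["strand"] = strand_out,
                           _["mismatches"] = out_mm,
                           _["stringsAsFactors"] = false);
}

// Best ungapped occurrence of `tag` within `ref` at Hamming distance
// <= max_mismatch on the given strand orientation (plus only; callers
// reverse-complement as needed). Returns (start0, mm) or (-1, -1).
// [[Rcpp::export(name = ".locate_in_ref_cpp")]]
IntegerVector locate_in_ref_cpp(std::string tag, std::string ref,
                                int max_mismatch) {
  int lt = tag.size(), lr = ref.size();
  int best_pos = -1, best_mm = max_mismatch + 1;
  for (int s = 0; s + lt <= lr; ++s) {
    int mm = 0;
    for (int i = 0; i < lt; ++i) {
      if (tag[i] != ref[s + i] && ++mm >= best_mm) break;
    }
    if (mm < best_mm) { best_mm = mm; best_pos = s; if (mm == 0) break; }
  }
  if (best_mm > max_mismatch) return IntegerVector::create(-1, -1);
  return IntegerVector::create(best_pos, best_mm);
}

// For each tag, does any reference sequence contain it as an ungapped
// substring at Hamming distance <= max_mismatch? Returns the 1-based
// index of the first matching reference, or 0.
// [[Rcpp::export(name = ".match_any_ref_cpp")]]
IntegerVector match_any_ref_cpp(CharacterVector tags, CharacterVector refs,
                                int max_mismatch) {
  IntegerVector out(tags.size(), 0);
  std::vector<std::string> rs(refs.size());
  for (int r = 0; r < refs.size(); ++r) rs[r] = as<std::string>(refs[r]);
  for (int t = 0; t < tags.size(); ++t) {
    std::string tag = as<std::string>(tags[t]);
    for (int r = 0; r < (int)rs.size(); ++r) {
      const std::string &ref = rs[r];
      if ((int)tag.size() > (int)ref.size()) continue;
      bool hit = false;
      for (int s = 0; s + tag.size() <= ref.size() && !hit; ++s) {
        int mm = 0;
        bool ok = true;
        for (size_t i = 0; i < tag.size(); ++i) {
          if (tag[i] != ref[s + i] && ++mm > max_mismatch) { ok = false; break; }
        }
        if (ok) hit = true;
      }
      if (hit) { out[t] = r + 1; break; }
    }
  }
  return out;
}

// Batch version of locate_in_ref for one reference against many tags:
// returns a 2-column matrix (start0, mm), -1 where there is no hit.
// [[Rcpp::export(name = ".locate_batch_cpp")]]
IntegerMatrix locate_batch_cpp(CharacterVector tags, std::string ref,
                               int max_mismatch) {
  const int nt = tags.size(), lr = ref.size();
  IntegerMatrix out(nt, 2);
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    const int lt = tag.size();
    int best_pos = -1, best_mm = max_mismatch + 1;
    for (int s = 0; s + lt <= lr; ++s) {
      int mm = 0;
      for (int i = 0; i < lt; ++i) {
        if (tag[i] != ref[s + i] && ++mm >= best_mm) break;
      }
      if (mm < best_mm) { best_mm = mm; best_pos = s; if (!mm) break; }
    }
    out(t, 0) = best_mm <= max_mismatch ? best_pos : -1;
    out(t, 1) = best_mm <= max_mismatch ? best_mm : -1;
  }
  return out;
}
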