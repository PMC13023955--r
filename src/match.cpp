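// Ungapped, sense-strand exact / one-mismatch matcher used in place of a
// short-read aligner for the toy reference sets: a sliding Hamming scan with
// early exit. Characters are compared literally, so any non-ACGT symbol in
// either sequence simply never matches.

#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// All occurrences of `query` in each of `refs` with Hamming distance <= max_mm.
// Returns parallel vectors: ref index (1-based), start (1-based), mismatches.
// [[Rcpp::export(name = ".match_scan_cpp")]]
List match_scan_cpp(std::string query, CharacterVector refs, int max_mm) {
  const int L = static_cast<int>(query.size());
  std::vector<int> ref_i, start, mm_out;
  const char* q = query.c_str();
  for (int r = 0; r < refs.size(); ++r) {
    const char* s = CHAR(STRING_ELT(refs, r));
    int n = static_cast<int>(std::strlen(s));
    for (int off = 0; off + L <= n; ++off) {
      int mm = 0;
      const char* w = s + off;
      for (int k = 0; k < L; ++k) {
        if (w[k] != q[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) {
        ref_i.push_back(r + 1);
        start.push_back(off + 1);
        mm_out.push_back(mm);
      }
    }
  }
  return List::create(_["ref"] = wrap(ref_i), _["start"] = wrap(start),
                      _["mismatches"] = wrap(mm_out));
}

// For each query: does it occur in any reference with distance <= max_mm?
// [[Rcpp::export(name = ".match_any_cpp")]]
LogicalVector match_any_cpp(CharacterVector queries, CharacterVector refs,
                            int max_mm) {
  int nq = queries.size();
  LogicalVector out(nq);
  std::vector<const char*> rs(refs.size());
  std::vector<int> rlen(refs.size());
  for (int r = 0; r < refs.size(); ++r) {
    rs[r] = CHAR(STRING_ELT(refs, r));
    rlen[r] = static_cast<int>(std::strlen(rs[r]));
  }
  for (int i = 0; i < nq; ++i) {
    const char* q = CHAR(STRING_ELT(queries, i));
    int L = static_cast<int>(std::strlen(q));
    bool found = false;
    for (size_t r = 0; r < rs.size() && !found; ++r) {
      int n = rlen[r];
      for (int off = 0; off + L <= n && !found; ++off) {
        int mm = 0;
        const char* w = rs[r] + off;
        int k = 0;
        for (; k < L; ++k) {
          if (w[k] != q[k] && ++mm > max_mm) break;
        }
        if (k == L) found = true;
      }
    }
    out[i] = found;
  }
  return out;
}
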