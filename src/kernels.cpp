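#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// First offset (0-based) at which `pattern` occurs in each read with at most
// `max_mm` mismatches, scanning offsets in [from0, to0] (to0 < 0: no limit).
// Returns -1 where the pattern is not found.
// [[Rcpp::export]]
IntegerVector locate_pattern_cpp(CharacterVector reads, std::string pattern,
                                 int max_mm, int from0 = 0, int to0 = -1) {
  const int n = reads.size();
  const int plen = pattern.size();
  const char *pat = pattern.c_str();
  IntegerVector out(n, -1);
  for (int i = 0; i < n; ++i) {
    if (reads[i] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, i));
    const int L = std::strlen(s);
    int hi = L - plen;
    if (to0 >= 0 && to0 < hi) hi = to0;
    for (int o = from0; o <= hi; ++o) {
      int mm = 0;
      for (int k = 0; k < plen; ++k) {
        if (s[o + k] != pat[k] && ++mm > max_mm) break;
      }
      if (mm <= max_mm) { out[i] = o; break; }
    }
  }
  return out;
}

// Mismatch count of `pattern` against each read at per-read 0-based offsets.
// Invalid offsets (negative, or running off the read) give NA.
// [[Rcpp::export]]
IntegerVector mismatch_at_cpp(CharacterVector reads, std::string pattern,
                              IntegerVector offsets0) {
  const int n = reads.size();
  const int plen = pattern.size();
  const char *pat = pattern.c_str();
  IntegerVector out(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int o = offsets0[i];
    if (o == NA_INTEGER || o < 0 || reads[i] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, i));
    if (o + plen > (int) std::strlen(s)) continue;
    int mm = 0;
    for (int k = 0; k < plen; ++k) mm += (s[o + k] != pat[k]);
    out[i] = mm;
  }
  return out;
}

// infix (semi-global) edit distance of `pat` against segment [lo, hi) of `s`,
// capped at cap + 1 (early exit once every cell exceeds cap)
static int infix_edit(const char *pat, int m, const char *s, int lo, int hi,
                      int cap) {
  const int n = hi - lo;
  if (n <= 0) return cap + 1;
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int c = 0; c <= n; ++c) prev[c] = 0; // free start anywhere in read
  for (int r = 1; r <= m; ++r) {
    cur[0] = r;
    int rowmin = cur[0];
    for (int c = 1; c <= n; ++c) {
      int sub = prev[c - 1] + (pat[r - 1] != s[lo + c - 1]);
      int del = prev[c] + 1;
      int ins = cur[c - 1] + 1;
      int v = sub < del ? sub : del;
      if (ins < v) v = ins;
      cur[c] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > cap) return cap + 1;
    std::swap(prev, cur);
  }
  int best = prev[0];
  for (int c = 1; c <= n; ++c) if (prev[c] < best) best = prev[c];
  return best > cap ? cap + 1 : best;
}

// Minimum edit distance of each reference junction within each insert.
// ref_off gives the expected 0-based offset of each reference inside the
// insert (-1 = unknown, search the whole insert); with a known offset the
// search is restricted to that neighbourhood (+/- slack + cap), after a fast
// exact-match check. Distances are capped at cap + 1.
// [[Rcpp::export]]
IntegerMatrix junction_dist_cpp(CharacterVector inserts, CharacterVector refs,
                                IntegerVector ref_off, int slack, int cap) {
  const int n = inserts.size(), m = refs.size();
  std::vector<std::string> rf(m);
  for (int r = 0; r < m; ++r) rf[r] = as<std::string>(refs[r]);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i) {
    if (inserts[i] == NA_STRING) {
      for (int r = 0; r < m; ++r) out(i, r) = cap + 1;
      continue;
    }
    const char *s = CHAR(STRING_ELT(inserts, i));
    const int L = std::strlen(s);
    for (int r = 0; r < m; ++r) {
      const int rl = rf[r].size();
      const int o = ref_off[r];
      int d;
      if (o >= 0) {
        if (o + rl <= L && std::memcmp(s + o, rf[r].c_str(), rl) == 0) {
          d = 0;
        } else {
          int lo = o - slack - cap; if (lo < 0) lo = 0;
          int hi = o + rl + slack + cap; if (hi > L) hi = L;
          d = infix_edit(rf[r].c_str(), rl, s, lo, hi, cap);
        }
      } else {
        d = infix_edit(rf[r].c_str(), rl, s, 0, L, cap);
      }
      out(i, r) = d;
    }
  }
  return out;
}

// i.i.d. substitution errors over every base, using R's RNG so results are
// reproducible under set.seed()
// [[Rcpp::export]]
CharacterVector mutate_seq_cpp(CharacterVector reads, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const int n = reads.size();
  CharacterVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t k = 0; k < s.size(); ++k) {
      if (unif_rand() < error_rate) {
        char c = s[k], nc;
        do {
          nc = bases[(int) (unif_rand() * 4) & 3];
        } while (nc == c);
        s[k] = nc;
      }
    }
    out[i] = s;
  }
  return out;
}
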