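#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Jaro similarity with Winkler prefix boost (p = 0.1, prefix <= 4, applied
// unconditionally). Operates on raw bytes; inputs are expected to be
// normalized to ASCII upper case before comparison.
static double jw_one(const char* a, int la, const char* b, int lb) {
  if (la == 0 && lb == 0) return 1.0;
  if (la == 0 || lb == 0) return 0.0;
  int window = std::max(la, lb) / 2 - 1;
  if (window < 0) window = 0;
  std::vector<char> am(la, 0), bm(lb, 0);
  int m = 0;
  for (int i = 0; i < la; ++i) {
    int lo = std::max(0, i - window);
    int hi = std::min(lb - 1, i + window);
    for (int j = lo; j <= hi; ++j) {
      if (!bm[j] && a[i] == b[j]) { am[i] = 1; bm[j] = 1; ++m; break; }
    }
  }
  if (m == 0) return 0.0;
  int half = 0, j = 0;
  for (int i = 0; i < la; ++i) {
    if (!am[i]) continue;
    while (!bm[j]) ++j;
    if (a[i] != b[j]) ++half;
    ++j;
  }
  double t = half / 2.0;
  double jaro = ((double)m / la + (double)m / lb + (m - t) / m) / 3.0;
  int l = 0, maxl = std::min(4, std::min(la, lb));
  while (l < maxl && a[l] == b[l]) ++l;
  return jaro + l * 0.1 * (1.0 - jaro);
}

// [[Rcpp::export]]
NumericVector jw_vec_cpp(CharacterVector a, String b) {
  const char* bs = b.get_cstring();
  int lb = (int)strlen(bs);
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (a[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* as = CHAR(STRING_ELT(a, i));
    out[i] = jw_one(as, (int)strlen(as), bs, lb);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector jw_pair_cpp(CharacterVector a, CharacterVector b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) { out[i] = NA_REAL; continue; }
    const char* as = CHAR(STRING_ELT(a, i));
    const char* bs = CHAR(STRING_ELT(b, i));
    out[i] = jw_one(as, (int)strlen(as), bs, (int)strlen(bs));
  }
  return out;
}
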