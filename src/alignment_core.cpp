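#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and an optional
// band. Tie-breaking in the traceback is deterministic: diagonal, then up
// (gap in b), then left (gap in a). The identity reported downstream is
// matches / alignment columns.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0, double gap = -2.0,
                  int band = 0, bool traceback = true) {
  const int n = a.size(), m = b.size();
  // corridor half-width; band <= 0 means full matrix
  long w;
  if (band > 0) {
    w = (long)band + std::abs(n - m);
  } else {
    w = (long)std::max(n, m) + 1;
  }
  std::vector<double> prev(m + 1), cur(m + 1);
  // traceback codes: 0 = diag, 1 = up (i-1,j), 2 = left (i,j-1), 3 = unset
  std::vector<unsigned char> tb;
  if (traceback) tb.assign((size_t)(n + 1) * (m + 1), 3);

  prev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    prev[j] = (j <= w) ? j * gap : NEG_INF;
    if (traceback && j <= w) tb[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    long jlo = std::max(1L, (long)i - w), jhi = std::min((long)m, (long)i + w);
    cur[0] = ((long)i <= w) ? i * gap : NEG_INF;
    if (traceback && (long)i <= w) tb[(size_t)i * (m + 1)] = 1;
    if (jlo > 1) cur[jlo - 1] = NEG_INF;
    for (long j = jlo; j <= jhi; ++j) {
      double sdiag = prev[j - 1] +
        ((a[i - 1] == b[j - 1]) ? match : mismatch);
      double sup = (j <= (long)i + w - 1) ? prev[j] + gap : NEG_INF;
      double sleft = (j - 1 >= (long)i - w + 1 || j - 1 == 0)
        ? cur[j - 1] + gap : NEG_INF;
      // order of preference: diag >= up >= left
      double best = sdiag; unsigned char code = 0;
      if (sup > best) { best = sup; code = 1; }
      if (sleft > best) { best = sleft; code = 2; }
      cur[j] = best;
      if (traceback) tb[(size_t)i * (m + 1) + j] = code;
    }
    if (jhi < m) for (long j = jhi + 1; j <= m; ++j) cur[j] = NEG_INF;
    std::swap(prev, cur);
  }
  double score = prev[m];

  if (!traceback) {
    return List::create(_["score"] = score);
  }
  // walk back from (n, m)
  std::vector<int> apos, bpos;
  apos.reserve(n + m); bpos.reserve(n + m);
  int i = n, j = m;
  int matches = 0, columns = 0, gaps = 0;
  while (i > 0 || j > 0) {
    unsigned char code = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && code == 0) {
      apos.push_back(i); bpos.push_back(j);
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (i > 0 && (code == 1 || j == 0)) {
      apos.push_back(i); bpos.push_back(NA_INTEGER);
      ++gaps; --i;
    } else {
      apos.push_back(NA_INTEGER); bpos.push_back(j);
      ++gaps; --j;
    }
    ++columns;
  }
  std::reverse(apos.begin(), apos.end());
  std::reverse(bpos.begin(), bpos.end());
  return List::create(
    _["score"] = score,
    _["matches"] = matches,
    _["columns"] = columns,
    _["gaps"] = gaps,
    _["a_pos"] = IntegerVector(apos.begin(), apos.end()),
    _["b_pos"] = IntegerVector(bpos.begin(), bpos.end()));
}

// Count mismatches of each read placed ungapped on its candidate reference at
// a 0-based start. Returns NA when the read does not fit inside the
// reference. ref_idx is 1-based into refs.
// [[Rcpp::export(name = ".hamming_at_cpp")]]
IntegerVector hamming_at_cpp(CharacterVector refs, IntegerVector ref_idx,
                             IntegerVector starts, CharacterVector reads) {
  const int n = reads.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* ref = CHAR(STRING_ELT(refs, ref_idx[i] - 1));
    const char* rd = CHAR(STRING_ELT(reads, i));
    int rl = LENGTH(STRING_ELT(refs, ref_idx[i] - 1));
    int L = LENGTH(STRING_ELT(reads, i));
    int s = starts[i];
    if (s < 0 || s + L > rl) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (int k = 0; k < L; ++k) if (rd[k] != ref[s + k]) ++mm;
    out[i] = mm;
  }
  return out;
}
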