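#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh recurrences) and a
// full traceback. A gap of length k costs gap_open + k * gap_extend, the
// convention used by blastn's "gap cost" / "gap extension cost" parameters.
// 'N' aligns as a mismatch against everything, including another 'N', and is
// never counted as an identity.
//
// The best-scoring cell is chosen by strict improvement in row-major order
// (smallest query end, then smallest subject end), which makes tie-breaking
// deterministic.
// [[Rcpp::export]]
List cpp_local_align(const std::string& query, const std::string& subject,
                     const int match, const int mismatch,
                     const int gap_open, const int gap_extend) {
  const int m = (int)query.size(), n = (int)subject.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)(m + 1) * (double)(n + 1) > 2.5e8)
    stop("alignment matrix too large; use the seeded search for long subjects");

  const int NEG = -1000000000;
  const int W = n + 1;
  const int open1 = gap_open + gap_extend;  // cost of a first gap base

  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<int> E((size_t)(m + 1) * W, NEG);  // gap in query (consumes subject)
  std::vector<int> F((size_t)(m + 1) * W, NEG);  // gap in subject (consumes query)
  // traceback pointers: pH 0=stop 1=diag 2=E 3=F; pE/pF 0=open(from H) 1=extend
  std::vector<unsigned char> pH((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> pE((size_t)(m + 1) * W, 0);
  std::vector<unsigned char> pF((size_t)(m + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const char qc = query[i - 1];
    const size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      const char sc = subject[j - 1];
      const int eopen = H[row + j - 1] - open1;
      const int eext  = E[row + j - 1] - gap_extend;
      if (eopen >= eext) { E[row + j] = eopen; pE[row + j] = 0; }
      else               { E[row + j] = eext;  pE[row + j] = 1; }
      const int fopen = H[prow + j] - open1;
      const int fext  = F[prow + j] - gap_extend;
      if (fopen >= fext) { F[row + j] = fopen; pF[row + j] = 0; }
      else               { F[row + j] = fext;  pF[row + j] = 1; }
      const bool isid = (qc == sc) && qc != 'N';
      const int diag = H[prow + j - 1] + (isid ? match : mismatch);
      int h = 0; unsigned char p = 0;
      if (diag > h) { h = diag; p = 1; }
      if (E[row + j] > h) { h = E[row + j]; p = 2; }
      if (F[row + j] > h) { h = F[row + j]; p = 3; }
      H[row + j] = h; pH[row + j] = p;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int aln_len = 0, identities = 0;
  int i = bi, j = bj;
  if (best > 0) {
    int state = 0;  // 0 = H, 1 = E, 2 = F
    while (true) {
      const size_t row = (size_t)i * W;
      if (state == 0) {
        const unsigned char p = pH[row + j];
        if (p == 0) break;
        if (p == 1) {
          ++aln_len;
          if (query[i - 1] == subject[j - 1] && query[i - 1] != 'N') ++identities;
          --i; --j;
        } else if (p == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        const unsigned char p = pE[row + j];
        ++aln_len; --j;
        if (p == 0) state = 0;
      } else {
        const unsigned char p = pF[row + j];
        ++aln_len; --i;
        if (p == 0) state = 0;
      }
    }
  }

  return List::create(
    _["score"] = best,
    _["q_start"] = best > 0 ? i + 1 : 0, _["q_end"] = bi,
    _["s_start"] = best > 0 ? j + 1 : 0, _["s_end"] = bj,
    _["aln_len"] = aln_len, _["identities"] = identities);
}
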