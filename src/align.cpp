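#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Smith-Waterman local alignment of two LAD profiles with substitution
// score sigma(i,j) = smax - |a_i - b_j| / m0 and linear gap penalty g per
// skipped position. Traceback ties prefer diagonal, then up (gap in
// subject), then left (gap in query); among equal-scoring end cells the
// first in row-major order wins, so alignments are deterministic.
// [[Rcpp::export]]
List cpp_sw_align(NumericVector a, NumericVector b, double smax, double m0,
                  double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> mv((size_t)(n + 1) * (m + 1), 0);  // 0 stop, 1 diag, 2 up, 3 left
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double sub = smax - std::fabs(a[i - 1] - b[j - 1]) / m0;
      const double diag = H[(size_t)(i - 1) * (m + 1) + (j - 1)] + sub;
      const double up = H[(size_t)(i - 1) * (m + 1) + j] - gap;
      const double left = H[(size_t)i * (m + 1) + (j - 1)] - gap;
      double h = 0.0;
      unsigned char d = 0;
      if (diag >= up && diag >= left && diag > 0) { h = diag; d = 1; }
      else if (up >= left && up > 0) { h = up; d = 2; }
      else if (left > 0) { h = left; d = 3; }
      H[(size_t)i * (m + 1) + j] = h;
      mv[(size_t)i * (m + 1) + j] = d;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qi, sj;
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const unsigned char d = mv[(size_t)i * (m + 1) + j];
    if (d == 0) break;
    if (d == 1) { qi.push_back(i); sj.push_back(j); --i; --j; }
    else if (d == 2) --i;
    else --j;
  }
  const int k = (int)qi.size();
  IntegerMatrix pairs(k, 2);
  for (int t = 0; t < k; ++t) {  // traceback collected pairs in reverse
    pairs(t, 0) = qi[k - 1 - t];
    pairs(t, 1) = sj[k - 1 - t];
  }
  return List::create(_["score"] = best, _["pairs"] = pairs);
}
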