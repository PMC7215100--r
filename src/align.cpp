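#include <Rcpp.h>
using namespace Rcpp;

// Needleman-Wunsch global alignment, linear gap penalty.
//
// a, b: 0-based indices into the substitution matrix rows/cols.
// Traceback tie-breaking is fixed for reproducibility: diagonal first,
// then up (residue of a against a gap), then left (residue of b against
// a gap). Returns 0-based aligned index vectors with -1 marking a gap.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, IntegerMatrix sub,
              double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix F(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) F(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) F(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = F(i - 1, j - 1) + sub(a[i - 1], b[j - 1]);
      double up = F(i - 1, j) + gap;
      double left = F(i, j - 1) + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F(i, j) = best;
    }
  }
  std::vector<int> ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        F(i, j) == F(i - 1, j - 1) + sub(a[i - 1], b[j - 1])) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && F(i, j) == F(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back(-1); --i;
    } else {
      ra.push_back(-1); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb),
                      _["score"] = F(n, m));
}
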